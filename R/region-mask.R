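## Region masks ---------------------------------------------------------------
##
## Interval sets are held as GRanges (1-based, closed), the standard R
## container for genomic intervals; BED files at the package boundary are
## 0-based half-open and rtracklayer performs the conversion in both
## directions.  A mask carries a `label` metadata column.

MASK_LABELS <- c("coding_exon", "conserved_element", "low_coverage",
                 "cpg", "neutral")

#' Build a region mask
#'
#' @param chrom Character vector of sequence names.
#' @param start,end 1-based closed interval bounds (`start <= end`).
#' @param label One of `r paste(MASK_LABELS, collapse = ", ")`.
#' @param seqlengths Optional named integer vector of contig lengths.
#' @return A [GenomicRanges::GRanges] with a `label` column, sorted and
#'   reduced (non-overlapping within the label).
#' @export
region_mask <- function(chrom, start, end, label,
                        seqlengths = NULL) {
  label <- match.arg(label, MASK_LABELS)
  if (any(end < start)) stop_uneecon("region_mask: end < start")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  gr$label <- label
  gr
}

#' Read/write a region mask as BED
#'
#' BED files are 0-based half-open; the in-memory representation is a
#' 1-based closed `GRanges`.  `read_region_bed` attaches the given label;
#' `write_region_bed` drops metadata beyond the interval itself.
#'
#' @param path BED file path.
#' @param label Mask label to attach to the intervals.
#' @return `read_region_bed`: a labelled `GRanges`; `write_region_bed`:
#'   `path`, invisibly.
#' @export
read_region_bed <- function(path, label) {
  label <- match.arg(label, MASK_LABELS)
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::mcols(gr) <- NULL
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  gr$label <- label
  gr
}

#' @rdname read_region_bed
#' @param mask A `GRanges` mask.
#' @export
write_region_bed <- function(mask, path) {
  gr <- mask
  GenomicRanges::mcols(gr) <- NULL
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

genome_granges <- function(genome) {
  nm <- sub("\\s.*$", "", names(genome))
  GenomicRanges::GRanges(nm, IRanges::IRanges(1L, Biostrings::width(genome)),
                         seqlengths = stats::setNames(Biostrings::width(genome), nm))
}

#' Locate CpG sites on a genome
#'
#' Returns intervals covering both bases of every CG dinucleotide on the
#' reference strand (which, by reverse complement, also covers the CG on the
#' opposite strand at the same positions).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return A `GRanges` with label `"cpg"`.
#' @export
cpg_sites <- function(genome) {
  nm <- sub("\\s.*$", "", names(genome))
  hits <- lapply(seq_along(genome), function(i) {
    m <- Biostrings::matchPattern("CG", genome[[i]])
    if (length(m) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(nm[i],
                           IRanges::IRanges(BiocGenerics::start(m),
                                            BiocGenerics::end(m)))
  })
  gr <- suppressWarnings(do.call(c, hits))
  GenomeInfoDb::seqlevels(gr) <- nm
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(Biostrings::width(genome), nm)
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  if (length(gr)) gr$label <- "cpg"
  gr
}

#' Construct the putatively neutral mask
#'
#' Starting from whole contigs, removes coding exons padded by
#' `exon_pad` bp on each side, conserved elements padded by
#' `conserved_pad` bp, sites with average sequencing depth below
#' `min_depth`, and both bases of every CpG dinucleotide.  What remains is
#' treated as neutral territory for mutation-model fitting.
#'
#' @param coding_exons,conserved_elements `GRanges` masks (labels are not
#'   checked; any interval set works).
#' @param coverage A `GRanges` whose `score` column holds mean depth; sites
#'   not covered by any interval are treated as depth 0 (excluded).
#' @param genome A [Biostrings::DNAStringSet] for contig bounds and CpG
#'   detection.
#' @param exon_pad,conserved_pad Buffer sizes in bp (defaults 1000 and 100).
#' @param min_depth Minimum average depth for a site to be retained
#'   (default 20).
#' @return A `GRanges` with label `"neutral"`.  An empty result is a fatal
#'   error reporting which filter removed the most territory.
#' @export
build_neutral_mask <- function(coding_exons, conserved_elements, coverage,
                               genome, exon_pad = 1000L, conserved_pad = 100L,
                               min_depth = 20) {
  all_gr <- genome_granges(genome)
  sl <- GenomeInfoDb::seqlengths(all_gr)
  harmonize <- function(gr) {
    GenomeInfoDb::seqlevels(gr, pruning.mode = "coarse") <-
      GenomeInfoDb::seqlevels(all_gr)
    GenomeInfoDb::seqlengths(gr) <- sl
    gr
  }
  pad <- function(gr, by) {
    if (length(gr) == 0L) return(harmonize(gr))
    GenomicRanges::trim(suppressWarnings(harmonize(gr) + by))
  }
  cov <- harmonize(coverage)
  if (!("score" %in% names(GenomicRanges::mcols(cov))))
    stop_uneecon("`coverage` must carry a numeric `score` column (mean depth)")
  high <- GenomicRanges::reduce(cov[cov$score >= min_depth])
  low <- GenomicRanges::setdiff(all_gr, high)

  filters <- list(
    coding_exon = pad(coding_exons, exon_pad),
    conserved_element = pad(conserved_elements, conserved_pad),
    low_coverage = low,
    cpg = cpg_sites(genome)
  )
  excluded <- GenomicRanges::reduce(
    suppressWarnings(do.call(c, unname(lapply(filters, function(g) {
      GenomicRanges::mcols(g) <- NULL
      harmonize(g)
    })))))
  neutral <- GenomicRanges::setdiff(all_gr, excluded)
  if (sum(BiocGenerics::width(neutral)) == 0L) {
    removed <- vapply(filters, function(g) sum(as.numeric(BiocGenerics::width(g))),
                      numeric(1))
    worst <- names(which.max(removed))
    stop_uneecon(
      "neutral mask is empty; filter removing the most territory: %s (%.0f bp of %.0f bp)",
      worst, removed[[worst]], sum(as.numeric(sl)))
  }
  neutral$label <- "neutral"
  neutral
}
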