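## Variant tables -------------------------------------------------------------
##
## A variant table is an ordinary data.frame with one row per candidate
## mutation.  Core columns: chrom, pos (1-based), ref, alt, gene_id, exon_id,
## context7 (7-mer centred on pos, reference strand), depth (mean sequencing
## depth), observed (0/1 presence in the population sample), consequence
## (missense/synonymous/noncoding).  Feature columns, when present, share a
## common prefix (default "feature_") and are real-valued.

CONSEQUENCES <- c("missense", "synonymous", "noncoding")

core_variant_columns <- function() {
  c("chrom", "pos", "ref", "alt", "gene_id", "exon_id",
    "context7", "depth", "observed", "consequence")
}

#' Read a variant table from TSV
#'
#' Reads a tab-separated variant table, maps file columns onto the canonical
#' schema, and validates every row against the variant invariants
#' (`context7` is a 7-mer of ACGT whose centre equals `ref`, `alt != ref`,
#' `depth >= 0`, `observed` in 0/1).  Row order is preserved.
#'
#' @param path Path to a TSV file with a header line.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(pos = "position")`.
#'   Unmentioned columns are taken under their canonical names.
#' @param feature_prefix Prefix identifying feature columns (default
#'   `"feature_"`).  Tables without feature columns (e.g. neutral-model
#'   records) are valid.
#' @return A validated `data.frame`; feature column names are recorded in
#'   `attr(, "feature_columns")`.
#' @seealso [write_variant_table()], [validate_variant_table()]
#' @export
read_variant_table <- function(path, schema = NULL, feature_prefix = "feature_") {
  if (!file.exists(path)) stop_uneecon("variant table not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    bad <- setdiff(unname(schema), names(df))
    if (length(bad))
      stop_uneecon("schema maps to columns absent from %s: %s",
                   path, paste(bad, collapse = ", "))
    idx <- match(unname(schema), names(df))
    names(df)[idx] <- names(schema)
  }
  missing <- setdiff(core_variant_columns(), names(df))
  if (length(missing))
    stop_uneecon("variant table %s is missing required column(s): %s",
                 path, paste(missing, collapse = ", "))
  validate_variant_table(df, feature_prefix = feature_prefix, source = path)
}

#' Validate a variant table in memory
#'
#' @param df A data.frame holding the canonical variant columns.
#' @inheritParams read_variant_table
#' @param source Label used in error messages (defaults to
#'   `"variant table"`).
#' @return `df`, with normalized column types and `attr(, "feature_columns")`.
#' @export
validate_variant_table <- function(df, feature_prefix = "feature_",
                                   source = "variant table") {
  missing <- setdiff(core_variant_columns(), names(df))
  if (length(missing))
    stop_uneecon("%s is missing required column(s): %s",
                 source, paste(missing, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$gene_id <- as.character(df$gene_id)
  df$exon_id <- as.character(df$exon_id)
  df$context7 <- toupper(as.character(df$context7))

  fail <- function(cond, what) {
    if (any(cond)) {
      rows <- which(cond)
      stop_uneecon("%s: %s at row(s) %s", source, what,
                   paste(utils::head(rows, 5L), collapse = ", "))
    }
  }
  fail(!grepl("^[ACGT]$", df$ref), "ref is not a single A/C/G/T base")
  fail(!grepl("^[ACGT]$", df$alt), "alt is not a single A/C/G/T base")
  fail(df$alt == df$ref, "alt equals ref")
  fail(!grepl("^[ACGT]{7}$", df$context7), "context7 is not a 7-mer of A/C/G/T")
  fail(substr(df$context7, 4L, 4L) != df$ref,
       "context7 centre base does not match ref")
  fail(!is.finite(df$pos) | df$pos != round(df$pos) | df$pos < 1,
       "pos is not a positive integer")
  fail(!is.finite(df$depth) | df$depth < 0, "depth is negative or missing")
  fail(!(df$observed %in% c(0, 1)), "observed is not 0/1")
  fail(!(df$consequence %in% CONSEQUENCES),
       sprintf("consequence not one of %s", paste(CONSEQUENCES, collapse = "/")))

  feat <- grep(paste0("^", feature_prefix), names(df), value = TRUE)
  for (fc in feat) {
    df[[fc]] <- as.numeric(df[[fc]])
    fail(!is.finite(df[[fc]]), sprintf("non-finite value in feature column %s", fc))
  }
  attr(df, "feature_columns") <- feat
  df
}

#' Write a variant table to TSV
#'
#' Inverse of [read_variant_table()]: a written table reads back with
#' identical records.
#'
#' @param df Variant table (data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Extract the 7-mer context around a position
#'
#' Returns the reference-strand bases at `[pos - 3, pos + 3]` (1-based,
#' inclusive), uppercased.  No strand collapsing is applied: contexts are
#' always reported on the reference strand, so a pyrimidine-centred folding
#' variant can be layered on top without changing this function.
#'
#' @param fasta A [Biostrings::DNAStringSet] or the path of a FASTA file.
#' @param chrom Sequence name.
#' @param pos 1-based position of the focal base; must satisfy
#'   `4 <= pos <= length(chrom) - 3`.
#' @return A 7-character string.
#' @export
#' @examples
#' dna <- Biostrings::DNAStringSet(c(chr1 = "AAACGTTT"))
#' extract_context7(dna, "chr1", 4)  # "AAACGTT"
extract_context7 <- function(fasta, chrom, pos) {
  if (is.character(fasta) && length(fasta) == 1L)
    fasta <- Biostrings::readDNAStringSet(fasta)
  if (!methods::is(fasta, "DNAStringSet"))
    stop_uneecon("`fasta` must be a DNAStringSet or a FASTA file path")
  nm <- sub("\\s.*$", "", names(fasta))
  i <- match(chrom, nm)
  if (is.na(i)) stop_uneecon("sequence %s not found in FASTA", chrom)
  len <- Biostrings::width(fasta)[i]
  if (!is_count(pos) || pos < 4 || pos > len - 3)
    stop_uneecon(
      "pos %s out of range for a 7-mer on %s (length %d): need 4 <= pos <= %d",
      format(pos), chrom, len, len - 3L)
  ctx <- toupper(as.character(Biostrings::subseq(fasta[[i]], pos - 3L, pos + 3L)))
  if (!grepl("^[ACGT]{7}$", ctx))
    stop_uneecon("ambiguous context at %s:%d (non-ACGT base in window): %s",
                 chrom, as.integer(pos), ctx)
  ctx
}
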