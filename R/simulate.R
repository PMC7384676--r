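## Synthetic data -------------------------------------------------------------
##
## The generator mirrors the model's own generative process so that every
## stage of the pipeline can be exercised, and parameter recovery verified,
## without external data.  No population-genetic forward simulation is
## attempted: occurrence indicators are drawn from exactly the Bernoulli
## models the inference assumes, with all ground truth recorded.

#' Simulate a genome with non-overlapping exons
#'
#' Random sequence with the requested GC content; exons of fixed length are
#' placed uniformly without overlap (and at least 4 bp from contig ends so
#' every exonic base has a full 7-mer context).
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bp.
#' @param gc GC content in (0, 1) (default 0.41, genome-typical).
#' @param n_exons Exons per contig.
#' @param exon_length Exon length in bp (default 150).
#' @param seed Seed; identical seeds give identical sequences.
#' @return List with `genome` (a [Biostrings::DNAStringSet], contigs named
#'   `contig_1`, ...) and `exons` (`GRanges` with `exon_id`).
#' @export
simulate_genome <- function(n_contigs = 1L, contig_length = 100000L,
                            gc = 0.41, n_exons = 5L, exon_length = 150L,
                            seed = 1L) {
  if (gc <= 0 || gc >= 1) stop_uneecon("`gc` must be in (0, 1)")
  if (n_exons * exon_length * 2 > contig_length - 8)
    stop_uneecon("cannot pack %d exons of %d bp into %d bp contigs",
                 n_exons, exon_length, contig_length)
  with_seed_or_not(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(seq_len(n_contigs), function(i) {
      paste(sample(names(probs), contig_length, replace = TRUE, prob = probs),
            collapse = "")
    }, "")
    genome <- Biostrings::DNAStringSet(stats::setNames(
      seqs, paste0("contig_", seq_len(n_contigs))))
    exon_list <- lapply(seq_len(n_contigs), function(i) {
      starts <- integer(0)
      tries <- 0L
      while (length(starts) < n_exons) {
        cand <- sample.int(contig_length - exon_length - 8L, 1L) + 4L
        if (!any(abs(cand - starts) < exon_length)) {
          starts <- c(starts, cand)
        } else if ((tries <- tries + 1L) > 1000L * n_exons) {
          stop_uneecon("exon packing failed on contig %d", i)
        }
      }
      GenomicRanges::GRanges(paste0("contig_", i),
                             IRanges::IRanges(sort(starts),
                                              width = exon_length))
    })
    exons <- suppressWarnings(do.call(c, exon_list))
    GenomeInfoDb::seqlengths(exons) <- stats::setNames(
      rep(contig_length, n_contigs), paste0("contig_", seq_len(n_contigs)))
    exons$exon_id <- paste0("exon_", seq_along(exons))
    exons$label <- "coding_exon"
    list(genome = genome, exons = exons)
  })
}

#' Simulate a ground-truth mutability table
#'
#' Enumerates every distinct 7-mer (with an unambiguous ACGT window)
#' occurring in the genome and assigns each (context, alternate allele)
#' class a true logit mutability drawn from a Gaussian.  Counts are zero:
#' this table is a truth object, not an estimate.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param mean_F,sd_F Mean and sd of the true logit mutabilities
#'   (defaults -2.5 and 1, giving rare-variant-like class frequencies).
#' @param seed Seed.
#' @return A `mutability_table` covering all observed contexts x 3 alts.
#' @export
simulate_mutability_table <- function(genome, mean_F = -2.5, sd_F = 1,
                                      seed = 1L) {
  ctxs <- unique(unlist(lapply(seq_along(genome), function(i) {
    s <- as.character(genome[[i]])
    n <- nchar(s)
    if (n < 7L) return(character())
    v <- substring(s, 1:(n - 6L), 7:n)
    v[grepl("^[ACGT]{7}$", v)]
  })))
  ref <- substr(ctxs, 4L, 4L)
  alts <- lapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r))
  tab <- data.frame(
    context7 = rep(ctxs, each = 3L),
    alt = unlist(alts),
    count_total = 0L, count_observed = 0L,
    stringsAsFactors = FALSE)
  tab$F <- with_seed_or_not(seed, stats::rnorm(nrow(tab), mean_F, sd_F))
  tab$f <- logistic(tab$F)
  class(tab) <- c("mutability_table", "data.frame")
  tab
}

#' Simulate neutral whole-genome variants
#'
#' Draws candidate sites uniformly from the mask, assigns each the 7-mer
#' context from the genome, a log-normal sequencing depth, and a
#' whole-genome occurrence indicator
#' `Y ~ Bernoulli(logistic(a + alpha1 log d + alpha2 F))`, where the
#' intercept `a` is the exon-local `alpha3` of the exon whose
#' `+/- window_bp` window contains the site (first match) and `alpha0`
#' elsewhere.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param mask Neutral `GRanges` to draw sites from.
#' @param params_true A [mutation_model_params()] with the true
#'   coefficients (and `alpha3` named by exon id).
#' @param mutability A truth `mutability_table` covering the genome.
#' @param exons `GRanges` with `exon_id` (used for window assignment); may
#'   be empty.
#' @param n_sites Number of candidate mutations to draw.
#' @param depth_meanlog,depth_sdlog Log-normal depth model (defaults
#'   `log(30)` and 0.3).
#' @param seed Seed.
#' @return A validated variant table (`consequence = "noncoding"`,
#'   `gene_id = "."`, `exon_id` of the covering window or `"."`).
#' @export
simulate_neutral_variants <- function(genome, mask, params_true, mutability,
                                      exons = NULL, n_sites = 10000L,
                                      depth_meanlog = log(30),
                                      depth_sdlog = 0.3, seed = 1L) {
  if (sum(as.numeric(BiocGenerics::width(mask))) == 0)
    stop_uneecon("`mask` is empty")
  with_seed_or_not(seed, {
    df <- sample_sites(genome, mask, n_sites)
    df$depth <- stats::rlnorm(nrow(df), depth_meanlog, depth_sdlog)
    df$exon_id <- assign_window_exon(df, exons, params_true$window_bp)
    a <- ifelse(df$exon_id == ".", params_true$alpha0,
                params_true$alpha3[df$exon_id])
    Fv <- lookup_mutability(mutability, df$context7, df$alt)
    p <- logistic(a + params_true$alpha1 * log(df$depth) +
                    params_true$alpha2 * Fv)
    df$observed <- stats::rbinom(nrow(df), 1L, p)
    df$gene_id <- "."
    df$consequence <- "noncoding"
    validate_variant_table(df[, core_variant_columns()],
                           source = "simulated neutral variants")
  })
}

#' Simulate exome synonymous variants for recalibration
#'
#' Sites are drawn from the exons; the whole-genome logit prediction `q`
#' uses the true parameters, and the exome indicator is
#' `Y ~ Bernoulli(logistic(beta0 + q))`.
#'
#' @inheritParams simulate_neutral_variants
#' @param exons `GRanges` with `exon_id`; sites are drawn inside them and
#'   tagged with the exon's id.
#' @return A validated variant table (`consequence = "synonymous"`).
#' @export
simulate_synonymous_variants <- function(genome, exons, params_true,
                                         mutability, n_sites = 5000L,
                                         depth_meanlog = log(30),
                                         depth_sdlog = 0.3, seed = 1L) {
  if (is.na(params_true$beta0))
    stop_uneecon("`params_true$beta0` must be set")
  with_seed_or_not(seed, {
    df <- sample_sites(genome, exons, n_sites)
    df$depth <- stats::rlnorm(nrow(df), depth_meanlog, depth_sdlog)
    hit <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L)),
      exons, select = "first")
    df$exon_id <- exons$exon_id[hit]
    q <- params_true$alpha3[df$exon_id] +
      params_true$alpha1 * log(df$depth) +
      params_true$alpha2 * lookup_mutability(mutability, df$context7, df$alt)
    df$observed <- stats::rbinom(nrow(df), 1L, logistic(params_true$beta0 + q))
    df$gene_id <- df$exon_id
    df$consequence <- "synonymous"
    validate_variant_table(df[, core_variant_columns()],
                           source = "simulated synonymous variants")
  })
}

## Uniform site + alt draws from a mask, with contexts from the genome;
## positions whose 7-mer window is invalid are rejected and redrawn.
## Contig sequences are materialized once so context extraction is a
## vectorized substring, not a per-site subseq call.
sample_sites <- function(genome, mask, n_sites) {
  nm <- sub("\\s.*$", "", names(genome))
  seqs <- stats::setNames(
    vapply(seq_along(genome), function(i) as.character(genome[[i]]), ""), nm)
  lens <- stats::setNames(Biostrings::width(genome), nm)
  mask_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(mask)),
                        start = BiocGenerics::start(mask),
                        end = BiocGenerics::end(mask))
  widths <- mask_df$end - mask_df$start + 1
  bases <- c("A", "C", "G", "T")
  out <- NULL
  need <- n_sites
  guard <- 0L
  while (need > 0L) {
    iv <- sample.int(nrow(mask_df), need, replace = TRUE,
                     prob = widths / sum(widths))
    pos <- mask_df$start[iv] +
      floor(stats::runif(need) * (mask_df$end[iv] - mask_df$start[iv] + 1))
    chrom <- mask_df$chrom[iv]
    ok <- pos >= 4 & pos <= lens[chrom] - 3
    ctx <- rep(NA_character_, need)
    ctx[ok] <- substring(seqs[chrom[ok]], pos[ok] - 3L, pos[ok] + 3L)
    ok <- ok & !is.na(ctx) & grepl("^[ACGT]{7}$", ctx)
    if (any(ok)) {
      ref <- substr(ctx[ok], 4L, 4L)
      ## uniform alt among the three non-reference bases, vectorized
      shift <- sample.int(3L, sum(ok), replace = TRUE)
      alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
      out <- rbind(out, data.frame(chrom = chrom[ok], pos = pos[ok],
                                   ref = ref, alt = alt,
                                   context7 = ctx[ok],
                                   stringsAsFactors = FALSE))
    }
    need <- n_sites - NROW(out)
    if ((guard <- guard + 1L) > 100L)
      stop_uneecon("failed to draw %d valid sites from the mask", n_sites)
  }
  rownames(out) <- NULL
  out[seq_len(n_sites), , drop = FALSE]
}

assign_window_exon <- function(df, exons, window_bp) {
  if (is.null(exons) || length(exons) == 0L) return(rep(".", nrow(df)))
  win <- suppressWarnings(exons + window_bp)
  hit <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L)),
    win, select = "first")
  ifelse(is.na(hit), ".", exons$exon_id[hit])
}

#' Simulate a missense training dataset with known truth
#'
#' Generates per-gene batches from exactly the mixed-effects generative
#' process: features standard normal (optionally correlated through a
#' single latent factor), fixed effect `z = X w + b`, gene random effects
#' `u_j ~ N(0, sigma_true)`, neutral probabilities `mu ~ Beta(mu_shape)`
#' (default Beta(2, 50), mean ~0.04, mimicking rare-variant occurrence),
#' and `Y ~ Bernoulli(logistic(z + u_j) * mu)`.
#'
#' @param n_genes,variants_per_gene Dataset dimensions.  Gene sizes are
#'   fixed by default; `size_sdlog > 0` draws them log-normal around
#'   `variants_per_gene` to stress unbalanced minibatches.
#' @param n_features Number of features.
#' @param weights,bias True fixed-effect weights (length `n_features`;
#'   default standard normal draws) and bias.
#' @param sigma_true True random-effect standard deviation (>= 0; 0 means
#'   no gene effect).
#' @param mu_shape Beta shape parameters for the neutral probabilities.
#' @param feature_cor Single-factor feature correlation in \[0, 1)
#'   (default 0, uncorrelated).
#' @param size_sdlog Log-normal spread of gene sizes (default 0, fixed).
#' @param seed Seed.
#' @return List with `batches` (named list of [gene_batch()]es) and
#'   `truth` (a `sim_truth`: `weights`, `bias`, `sigma_true`, `u_true`,
#'   `seed`).
#' @export
simulate_missense_dataset <- function(n_genes = 50L, variants_per_gene = 100L,
                                      n_features = 5L, weights = NULL,
                                      bias = 0, sigma_true = 1,
                                      mu_shape = c(2, 50), feature_cor = 0,
                                      size_sdlog = 0, seed = 1L) {
  if (sigma_true < 0) stop_uneecon("`sigma_true` must be >= 0")
  if (feature_cor < 0 || feature_cor >= 1)
    stop_uneecon("`feature_cor` must be in [0, 1)")
  if (length(mu_shape) != 2L || any(mu_shape <= 0))
    stop_uneecon("`mu_shape` must be two positive Beta shapes")
  with_seed_or_not(seed, {
    if (is.null(weights)) weights <- stats::rnorm(n_features)
    if (length(weights) != n_features)
      stop_uneecon("`weights` must have length %d", n_features)
    gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
    u_true <- if (sigma_true > 0) stats::rnorm(n_genes, 0, sigma_true)
              else numeric(n_genes)
    names(u_true) <- gene_ids
    sizes <- if (size_sdlog > 0) {
      pmax(2L, round(stats::rlnorm(n_genes, log(variants_per_gene), size_sdlog)))
    } else rep(as.integer(variants_per_gene), n_genes)
    batches <- lapply(seq_len(n_genes), function(j) {
      n <- sizes[j]
      X <- matrix(stats::rnorm(n * n_features), n, n_features)
      if (feature_cor > 0) {
        fac <- stats::rnorm(n)
        X <- sqrt(1 - feature_cor) * X + sqrt(feature_cor) * fac
      }
      colnames(X) <- paste0("feature_", seq_len(n_features))
      mu <- stats::rbeta(n, mu_shape[1], mu_shape[2])
      mu <- pmin(pmax(mu, 1e-8), 1 - 1e-8)
      z <- drop(X %*% weights) + bias
      Y <- stats::rbinom(n, 1L, logistic(z + u_true[j]) * mu)
      gene_batch(gene_ids[j], X, mu, Y)
    })
    truth <- structure(list(weights = weights, bias = bias,
                            sigma_true = sigma_true, u_true = u_true,
                            seed = seed),
                       class = "sim_truth")
    list(batches = stats::setNames(batches, gene_ids), truth = truth)
  })
}

#' Build a balanced labelled benchmark table
#'
#' Samples `n_pos` rows from the positive class and `n_neg` from the
#' negative class, without replacement, for downstream ROC / enrichment
#' testing.
#'
#' @param scores Data.frame with at least `score` and a logical/0-1
#'   `truth` column defining class membership.
#' @param n_pos,n_neg Rows to sample per class.
#' @param seed Seed.
#' @return Data.frame of sampled rows with a `label` column (1 positive,
#'   0 negative).
#' @export
make_labeled_benchmark <- function(scores, n_pos, n_neg, seed = 1L) {
  if (!all(c("score", "truth") %in% names(scores)))
    stop_uneecon("`scores` needs `score` and `truth` columns")
  pos <- which(as.logical(scores$truth))
  neg <- which(!as.logical(scores$truth))
  if (length(pos) < n_pos || length(neg) < n_neg)
    stop_uneecon("insufficient class members (%d positive, %d negative) for %d + %d",
                 length(pos), length(neg), n_pos, n_neg)
  with_seed_or_not(seed, {
    take <- c(sample(pos, n_pos), sample(neg, n_neg))
    out <- scores[take, , drop = FALSE]
    out$label <- rep(c(1L, 0L), c(n_pos, n_neg))
    rownames(out) <- NULL
    out
  })
}
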