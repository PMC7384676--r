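## Evaluation utilities -------------------------------------------------------

#' Balanced AUC with class downsampling
#'
#' Downsamples the larger class to the size of the smaller (without
#' replacement, seeded), then computes the area under the ROC curve as the
#' normalized Mann-Whitney U statistic (midranks, so ties count 0.5).
#' The AUC is invariant under strictly monotone transforms of the scores.
#'
#' @param pos_scores,neg_scores Numeric score vectors (both nonempty).
#' @param seed Seed for the downsampling.
#' @return List with `auc`, `pos` and `neg` (the sampled score sets).
#' @export
balanced_auc <- function(pos_scores, neg_scores, seed = 1L) {
  if (!length(pos_scores) || !length(neg_scores))
    stop_uneecon("both score sets must be nonempty")
  with_seed_or_not(seed, {
    m <- min(length(pos_scores), length(neg_scores))
    if (length(pos_scores) > m) pos_scores <- sample(pos_scores, m)
    if (length(neg_scores) > m) neg_scores <- sample(neg_scores, m)
  })
  r <- rank(c(pos_scores, neg_scores))
  np <- length(pos_scores); nn <- length(neg_scores)
  u <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  list(auc = u / (np * nn), pos = pos_scores, neg = neg_scores)
}

#' Enrichment odds ratio at a percentile cutoff
#'
#' Thresholds at the stated upper percentile of the pooled case + control
#' score distribution (top `percentile`% are called deleterious), tabulates
#' (case/control) x (above/below), and reports the sample log2 odds ratio
#' with its standard error `sqrt(sum(1/cell)) / ln 2`.  When any cell is
#' zero, the Haldane-Anscombe 0.5 correction is applied to all four cells.
#'
#' @param case_scores,control_scores Numeric score vectors.
#' @param percentile Upper percentile in (0, 100): e.g. 10 keeps the top
#'   10% of pooled scores above the threshold.
#' @return An `enrichment_result`: `cutoff_percentile`, `threshold`,
#'   `table` (2x2 counts), `log2_or`, `se_log2_or`, `corrected`,
#'   `degenerate` (TRUE when all pooled scores are equal).
#' @export
percentile_enrichment <- function(case_scores, control_scores, percentile) {
  if (percentile <= 0 || percentile >= 100)
    stop_uneecon("`percentile` must be in (0, 100)")
  pooled <- c(case_scores, control_scores)
  degenerate <- length(unique(pooled)) == 1L
  thr <- stats::quantile(pooled, probs = 1 - percentile / 100, names = FALSE)
  tab <- matrix(c(sum(case_scores >= thr), sum(case_scores < thr),
                  sum(control_scores >= thr), sum(control_scores < thr)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("case", "control"), c("above", "below")))
  corrected <- any(tab == 0L)
  ct <- if (corrected) tab + 0.5 else tab
  log2_or <- log2((ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1]))
  se <- sqrt(sum(1 / ct)) / log(2)
  structure(list(cutoff_percentile = percentile, threshold = thr,
                 table = tab, log2_or = log2_or, se_log2_or = se,
                 corrected = corrected, degenerate = degenerate),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Top %.0f%% enrichment: log2 OR = %.3f (SE %.3f)%s%s\n",
              x$cutoff_percentile, x$log2_or, x$se_log2_or,
              if (x$corrected) " [0.5 correction]" else "",
              if (x$degenerate) " [degenerate: all scores equal]" else ""))
  print(x$table)
  invisible(x)
}

#' Length-matched negative gene set
#'
#' Greedy 1:1 nearest-neighbour matching on log gene length, without
#' replacement, with positives processed in random (seeded) order.  Log
#' length is used because gene lengths are strongly right-skewed.
#'
#' @param positives Data.frame with `gene_id` and `length`.
#' @param pool Data.frame of candidate negatives (same columns); must be at
#'   least as large as `positives`.
#' @param seed Seed for the processing order.
#' @return The matched subset of `pool`, one row per positive, with a
#'   `matched_to` column.
#' @export
match_negatives_by_length <- function(positives, pool, seed = 1L) {
  for (df in list(positives, pool))
    if (!all(c("gene_id", "length") %in% names(df)))
      stop_uneecon("`positives` and `pool` need `gene_id` and `length` columns")
  if (nrow(pool) < nrow(positives))
    stop_uneecon("pool (%d) smaller than positive set (%d)",
                 nrow(pool), nrow(positives))
  ord <- with_seed_or_not(seed, sample.int(nrow(positives)))
  avail <- rep(TRUE, nrow(pool))
  log_pool <- log(pool$length)
  picked <- integer(nrow(positives))
  for (i in ord) {
    d <- abs(log_pool - log(positives$length[i]))
    d[!avail] <- Inf
    j <- which.min(d)
    picked[i] <- j
    avail[j] <- FALSE
  }
  out <- pool[picked, , drop = FALSE]
  out$matched_to <- positives$gene_id
  rownames(out) <- NULL
  out
}

#' Median split of gene scores
#'
#' Sorts genes by score (descending; ties broken by gene identifier so the
#' split is deterministic) and returns the upper and lower halves; for odd
#' `n` the upper half receives the extra gene.
#'
#' @param gene_scores Named numeric vector (names are gene ids), or a
#'   data.frame with `gene_id` and `score`.
#' @return List with `upper` and `lower` character vectors of gene ids.
#' @export
median_split <- function(gene_scores) {
  if (is.data.frame(gene_scores)) {
    scores <- stats::setNames(gene_scores$score, gene_scores$gene_id)
  } else {
    scores <- gene_scores
  }
  if (length(scores) < 2L) stop_uneecon("need at least 2 genes to split")
  if (is.null(names(scores))) stop_uneecon("gene scores must be named")
  ord <- order(-scores, names(scores))
  ids <- names(scores)[ord]
  n_up <- ceiling(length(ids) / 2)
  list(upper = ids[seq_len(n_up)], lower = ids[-seq_len(n_up)])
}
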