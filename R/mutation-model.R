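## Context-dependent neutral mutation model -----------------------------------
##
## Occurrence of a neutral mutation in the population sample is modelled on
## the logit scale from three ingredients: the 7-mer mutability of its
## (context, alternate allele) class, the log mean sequencing depth at the
## site, and an exon-local intercept absorbing regional mutation-rate
## variation.  The whole-genome model is then recalibrated against observed
## synonymous variants in the exome sample with a single intercept shift,
## yielding mu, the neutral occurrence probability of every candidate
## missense mutation.  All fits are plain logistic regressions via stats::glm
## (IRLS), with a tight convergence tolerance so results are deterministic.

glm_ctrl <- function() stats::glm.control(epsilon = 1e-10, maxit = 100)

#' Compute the 7-mer mutability table
#'
#' For every (7-mer context, alternate allele) class present in the neutral
#' variant set, the mutability `f` is the proportion of class instances
#' carrying an observed rare variant, smoothed with a symmetric pseudocount:
#' `f = (n_observed + a) / (n_total + 2a)`.  `F = logit(f)` is the class's
#' contribution to the occurrence probability on the logit scale.  The
#' default Jeffreys pseudocount `a = 0.5` keeps `F` finite for classes with
#' no (or only) observed variants.
#'
#' @param neutral_variants Variant table restricted to the neutral mask,
#'   with `observed` marking rare-variant presence.
#' @param pseudocount Smoothing pseudocount `a >= 0` (default 0.5).
#' @return A `mutability_table`: data.frame with columns `context7`, `alt`,
#'   `count_total`, `count_observed`, `f`, `F`.
#' @export
compute_mutability <- function(neutral_variants, pseudocount = 0.5) {
  if (pseudocount < 0) stop_uneecon("`pseudocount` must be >= 0")
  key <- paste(neutral_variants$context7, neutral_variants$alt, sep = ">")
  total <- tapply(neutral_variants$observed, key, length)
  obs <- tapply(neutral_variants$observed, key, sum)
  parts <- strsplit(names(total), ">", fixed = TRUE)
  tab <- data.frame(
    context7 = vapply(parts, `[`, "", 1L),
    alt = vapply(parts, `[`, "", 2L),
    count_total = as.integer(total),
    count_observed = as.integer(obs),
    stringsAsFactors = FALSE
  )
  tab$f <- (tab$count_observed + pseudocount) /
    (tab$count_total + 2 * pseudocount)
  tab$F <- logit(tab$f)
  attr(tab, "pseudocount") <- pseudocount
  class(tab) <- c("mutability_table", "data.frame")
  tab[order(tab$context7, tab$alt), , drop = FALSE]
}

#' Look up logit-mutability values for variants
#'
#' @param mutability A `mutability_table` (from [compute_mutability()] or
#'   [simulate_mutability_table()]).
#' @param context7,alt Character vectors (recycled together).
#' @return Numeric vector of `F = logit(f)` values.  A class absent from the
#'   table is an explicit error, never a silent zero.
#' @export
lookup_mutability <- function(mutability, context7, alt) {
  key <- paste(context7, alt, sep = ">")
  tab_key <- paste(mutability$context7, mutability$alt, sep = ">")
  idx <- match(key, tab_key)
  if (anyNA(idx)) {
    miss <- unique(key[is.na(idx)])
    stop_uneecon("mutability class(es) missing from table: %s%s",
                 paste(utils::head(miss, 5L), collapse = ", "),
                 if (length(miss) > 5L) sprintf(" (+%d more)", length(miss) - 5L) else "")
  }
  f <- mutability$f[idx]
  if (any(!is.finite(mutability$F[idx])))
    stop_uneecon("infinite logit mutability encountered (class with f of 0 or 1); refit with a positive pseudocount")
  mutability$F[idx]
}

#' Fit the genome-wide neutral occurrence regression
#'
#' Logistic regression of the presence/absence of each neutral mutation in
#' the whole-genome sample on log depth and logit mutability:
#' `P(Y = 1) = logistic(alpha0 + alpha1 * log(d) + alpha2 * F)`.
#'
#' @param neutral_variants Variant table on the neutral mask; records with
#'   `depth <= 0` are an error (log depth undefined) and should be filtered
#'   upstream.
#' @param mutability A `mutability_table` covering every record's class.
#' @return A list with `alpha0`, `alpha1`, `alpha2`, their standard errors
#'   (`se`, named vector), the covariance matrix `vcov`, `converged`, and
#'   the fitted `glm` object (`fit`).
#' @export
fit_global_wgs <- function(neutral_variants, mutability) {
  if (any(neutral_variants$depth <= 0))
    stop_uneecon("depth <= 0 in %d record(s); exclude them before fitting (log depth undefined)",
                 sum(neutral_variants$depth <= 0))
  df <- data.frame(
    y = neutral_variants$observed,
    log_depth = log(neutral_variants$depth),
    F = lookup_mutability(mutability, neutral_variants$context7,
                          neutral_variants$alt)
  )
  fit <- stats::glm(y ~ log_depth + F, family = stats::binomial(),
                    data = df, control = glm_ctrl())
  if (!fit$converged)
    stop_uneecon("genome-wide occurrence regression did not converge in %d IRLS iterations (possible separation); deviance %.6g",
                 fit$iter, fit$deviance)
  cf <- stats::coef(fit)
  list(alpha0 = unname(cf[1L]), alpha1 = unname(cf[2L]), alpha2 = unname(cf[3L]),
       se = stats::setNames(sqrt(diag(stats::vcov(fit))),
                            c("alpha0", "alpha1", "alpha2")),
       vcov = stats::vcov(fit), converged = fit$converged, fit = fit)
}

#' Fit one exon-local intercept
#'
#' With the depth and mutability coefficients frozen at their genome-wide
#' estimates, fits the intercept-only logistic regression
#' `P(Y = 1) = logistic(alpha3_m + alpha1 * log(d) + alpha2 * F)` on the
#' neutral mutations within the exon's window, absorbing local
#' mutation-rate variation.  Windows with no usable information (no
#' records, or outcomes all 0 or all 1, under which the MLE diverges) fall
#' back to the global intercept `alpha0` with `fallback = TRUE`.
#'
#' @param window_variants Neutral variant table restricted to the exon's
#'   +/- `window_bp` window.
#' @param exon_id Exon identifier (provenance only).
#' @param alpha1,alpha2 Frozen genome-wide coefficients.
#' @param mutability A `mutability_table`.
#' @param alpha0 Global intercept used as fallback.
#' @return List with `exon_id`, `alpha3`, `se` (NA under fallback),
#'   `n`, `fallback`.
#' @export
fit_local_exon <- function(window_variants, exon_id, alpha1, alpha2,
                           mutability, alpha0) {
  n <- nrow(window_variants)
  y <- window_variants$observed
  if (n == 0L || length(unique(y)) < 2L)
    return(list(exon_id = exon_id, alpha3 = alpha0, se = NA_real_,
                n = n, fallback = TRUE))
  off <- alpha1 * log(window_variants$depth) +
    alpha2 * lookup_mutability(mutability, window_variants$context7,
                               window_variants$alt)
  fit <- stats::glm(y ~ 1 + offset(off), family = stats::binomial(),
                    control = glm_ctrl())
  if (!fit$converged)
    return(list(exon_id = exon_id, alpha3 = alpha0, se = NA_real_,
                n = n, fallback = TRUE))
  list(exon_id = exon_id, alpha3 = unname(stats::coef(fit)[1L]),
       se = sqrt(stats::vcov(fit)[1L, 1L]), n = n, fallback = FALSE)
}

#' Bundle fitted mutation-model parameters
#'
#' @param alpha0,alpha1,alpha2 Genome-wide coefficients.
#' @param alpha3 Named numeric vector of exon-local intercepts
#'   (one per exon).
#' @param beta0 Exome recalibration intercept (NA until
#'   [recalibrate_exome()] has run).
#' @param window_bp Exon window half-width in bp (default 60000).
#' @param provenance Free-form list (fallback flags, fit sizes, seeds).
#' @return A `mutation_model_params` object.
#' @export
mutation_model_params <- function(alpha0, alpha1, alpha2, alpha3,
                                  beta0 = NA_real_, window_bp = 60000L,
                                  provenance = list()) {
  if (window_bp <= 0) stop_uneecon("`window_bp` must be positive")
  if (is.null(names(alpha3)) && length(alpha3))
    stop_uneecon("`alpha3` must be a named vector (one entry per exon)")
  structure(list(alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
                 alpha3 = alpha3, beta0 = beta0,
                 window_bp = as.integer(window_bp), provenance = provenance),
            class = "mutation_model_params")
}

#' @export
print.mutation_model_params <- function(x, ...) {
  cat("Neutral mutation model parameters\n")
  cat(sprintf("  alpha0 = %.4f  alpha1 = %.4f  alpha2 = %.4f  beta0 = %s\n",
              x$alpha0, x$alpha1, x$alpha2,
              if (is.na(x$beta0)) "<unset>" else sprintf("%.4f", x$beta0)))
  cat(sprintf("  %d exon-local intercept(s), window +/- %d bp\n",
              length(x$alpha3), x$window_bp))
  invisible(x)
}

#' Logit-scale neutral prediction for variants
#'
#' `q = alpha3[exon] + alpha1 * log(depth) + alpha2 * F`: the whole-genome
#' model's prediction on the logit scale, before exome recalibration.
#' Purely deterministic in its inputs.
#'
#' @param variants Variant table (needs `exon_id`, `depth`, `context7`, `alt`).
#' @param params A `mutation_model_params`.
#' @param mutability A `mutability_table`.
#' @return Numeric vector `q`, one value per row.
#' @export
compute_q <- function(variants, params, mutability) {
  stopifnot(inherits(params, "mutation_model_params"))
  a3 <- params$alpha3[variants$exon_id]
  if (anyNA(a3)) {
    miss <- unique(variants$exon_id[is.na(a3)])
    stop_uneecon("no local intercept fitted for exon(s): %s",
                 paste(utils::head(miss, 5L), collapse = ", "))
  }
  Fv <- lookup_mutability(mutability, variants$context7, variants$alt)
  unname(a3 + params$alpha1 * log(variants$depth) + params$alpha2 * Fv)
}

#' Recalibrate the model against exome synonymous variants
#'
#' One-parameter logistic regression
#' `P(Y_exome = 1) = logistic(beta0 + q)` with `q` as a fixed offset,
#' absorbing the difference in sample size and coverage between the
#' whole-genome and exome samples.  At the optimum the MLE score equation
#' forces the sum of predicted probabilities to equal the observed
#' synonymous count exactly.
#'
#' @param synonymous_variants Variant table of synonymous sites with
#'   exome presence/absence in `observed`.
#' @param q Numeric vector from [compute_q()], aligned with the rows.
#' @return List with `beta0`, `se`, `converged`, and the `glm` `fit`.
#' @export
recalibrate_exome <- function(synonymous_variants, q) {
  if (length(q) != nrow(synonymous_variants))
    stop_uneecon("`q` length (%d) does not match variant rows (%d)",
                 length(q), nrow(synonymous_variants))
  y <- synonymous_variants$observed
  fit <- stats::glm(y ~ 1 + offset(q), family = stats::binomial(),
                    control = glm_ctrl())
  if (!fit$converged)
    stop_uneecon("exome recalibration did not converge: intercept iterate %.4g after %d iterations",
                 stats::coef(fit)[1L], fit$iter)
  list(beta0 = unname(stats::coef(fit)[1L]),
       se = sqrt(stats::vcov(fit)[1L, 1L]),
       converged = fit$converged, fit = fit)
}

#' Neutral occurrence probability of candidate mutations
#'
#' `mu = logistic(beta0 + q)`, the fully recalibrated probability that each
#' candidate mutation would be observed in the exome sample under
#' neutrality.  Strictly inside (0, 1).
#'
#' @inheritParams compute_q
#' @return A data.frame with the variant key columns plus `q` and `mu`.
#' @export
compute_mu <- function(variants, params, mutability) {
  if (is.na(params$beta0))
    stop_uneecon("`beta0` is unset; run recalibrate_exome() first")
  q <- compute_q(variants, params, mutability)
  data.frame(chrom = variants$chrom, pos = variants$pos,
             ref = variants$ref, alt = variants$alt,
             gene_id = variants$gene_id,
             q = q, mu = logistic(params$beta0 + q),
             stringsAsFactors = FALSE)
}

#' Fit the full neutral mutation model
#'
#' Orchestrates the pipeline: mutability table from the neutral set (unless
#' supplied), genome-wide regression, one local intercept per exon using
#' neutral mutations within `window_bp` of the exon, and exome
#' recalibration on the synonymous set.
#'
#' @param neutral_variants Neutral (noncoding) variant table with
#'   whole-genome presence/absence.
#' @param synonymous_variants Synonymous variant table with exome
#'   presence/absence; `exon_id` must name exons present in `exons`.
#' @param exons A `GRanges` of coding exons with an `exon_id` metadata
#'   column.
#' @param mutability Optional precomputed `mutability_table`.
#' @param pseudocount Passed to [compute_mutability()].
#' @param window_bp Exon window half-width (default 60000).
#' @return List with `params` (a `mutation_model_params`), `mutability`,
#'   `global` and `recalibration` fit summaries, and `local` (data.frame of
#'   per-exon intercepts with fallback flags).
#' @export
fit_mutation_model <- function(neutral_variants, synonymous_variants, exons,
                               mutability = NULL, pseudocount = 0.5,
                               window_bp = 60000L) {
  if (is.null(exons$exon_id))
    stop_uneecon("`exons` must carry an `exon_id` metadata column")
  if (is.null(mutability))
    mutability <- compute_mutability(neutral_variants, pseudocount)
  glob <- fit_global_wgs(neutral_variants, mutability)

  nv_gr <- GenomicRanges::GRanges(neutral_variants$chrom,
                                  IRanges::IRanges(neutral_variants$pos, width = 1L))
  win <- suppressWarnings(exons + window_bp)
  hits <- GenomicRanges::findOverlaps(nv_gr, win)
  V12 <- glob$vcov[2:3, 2:3]
  locals <- lapply(seq_along(exons), function(m) {
    rows <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == m]
    wv <- neutral_variants[rows, , drop = FALSE]
    l <- fit_local_exon(wv, exon_id = exons$exon_id[m],
                        alpha1 = glob$alpha1, alpha2 = glob$alpha2,
                        mutability = mutability, alpha0 = glob$alpha0)
    ## The local intercept is estimated with the first-stage coefficients
    ## frozen, so its conditional SE ignores their sampling error.  The
    ## delta method propagates it: the intercept absorbs roughly
    ## cbar' (alphahat - alpha) with cbar the window means of the frozen
    ## covariates.
    if (!l$fallback && nrow(wv)) {
      cbar <- c(mean(log(wv$depth)),
                mean(lookup_mutability(mutability, wv$context7, wv$alt)))
      l$se_propagated <- sqrt(l$se^2 + drop(cbar %*% V12 %*% cbar))
    } else {
      l$se_propagated <- NA_real_
    }
    l
  })
  local_df <- data.frame(
    exon_id = vapply(locals, `[[`, "", "exon_id"),
    alpha3 = vapply(locals, `[[`, 0, "alpha3"),
    se = vapply(locals, `[[`, 0, "se"),
    se_propagated = vapply(locals, `[[`, 0, "se_propagated"),
    n = vapply(locals, function(l) as.integer(l$n), 0L),
    fallback = vapply(locals, `[[`, FALSE, "fallback"),
    stringsAsFactors = FALSE
  )
  params <- mutation_model_params(
    alpha0 = glob$alpha0, alpha1 = glob$alpha1, alpha2 = glob$alpha2,
    alpha3 = stats::setNames(local_df$alpha3, local_df$exon_id),
    window_bp = window_bp,
    provenance = list(n_neutral = nrow(neutral_variants),
                      n_fallback_exons = sum(local_df$fallback))
  )
  q_syn <- compute_q(synonymous_variants, params, mutability)
  recal <- recalibrate_exome(synonymous_variants, q_syn)
  params$beta0 <- recal$beta0
  list(params = params, mutability = mutability,
       global = glob[c("alpha0", "alpha1", "alpha2", "se", "converged")],
       recalibration = recal[c("beta0", "se", "converged")],
       local = local_df)
}
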