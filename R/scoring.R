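## Posterior scoring ----------------------------------------------------------

#' Posterior distribution of a gene's random effect
#'
#' Discrete posterior of `u_j` over the quadrature nodes: the mass at node
#' `k` is proportional to its quadrature weight times the gene likelihood
#' at `u = u_k`, normalized in log space.  A gene with no occurrence data
#' (empty batch or `Y = NULL`) recovers the prior: mean 0, sd `sigma` (up
#' to quadrature error, which is zero for the second moment of a Gaussian).
#'
#' @param batch A [gene_batch()]; `X` on the model's (standardized) scale.
#' @param params A [dme_params()].
#' @param order Quadrature order (default 20).
#' @return A `posterior_u` object: `gene_id`, `nodes`, `log_weights`
#'   (normalized), `mean`, `sd`.
#' @export
posterior_u <- function(batch, params, order = 20L) {
  stopifnot(inherits(batch, "gene_batch"))
  gh <- gauss_hermite_gaussian(params$sigma, order)
  if (is.null(batch$Y) || nrow(batch$X) == 0L) {
    lw <- gh$log_w
  } else {
    z <- forward_cache(batch$X, params, mode = "infer")$z
    S <- gene_ll_nodes(z, batch$mu, batch$Y, gh$u)$S
    a <- gh$log_w + S
    norm <- logsumexp(a)
    if (!is.finite(norm))
      stop_uneecon("posterior underflow for gene %s: all %d quadrature nodes carry zero mass; increase `order`",
                   batch$gene_id, order)
    lw <- a - norm
  }
  w <- exp(lw)
  m <- sum(w * gh$u)
  v <- max(sum(w * gh$u^2) - m^2, 0)
  structure(list(gene_id = batch$gene_id, nodes = gh$u, log_weights = lw,
                 mean = m, sd = sqrt(v)),
            class = "posterior_u")
}

## Prior "posterior" used for leave-gene-out scoring.
prior_u <- function(params, order = 20L, gene_id = NA_character_) {
  gh <- gauss_hermite_gaussian(params$sigma, order)
  structure(list(gene_id = gene_id, nodes = gh$u, log_weights = gh$log_w,
                 mean = 0, sd = params$sigma),
            class = "posterior_u")
}

#' Variant deleteriousness score
#'
#' `1 - E[logistic(z + u) | data]`, the posterior expected reduction in
#' occurrence probability relative to neutrality.  Bounded in \[0, 1\] and
#' monotone decreasing in `z`; higher scores mean stronger inferred
#' negative selection.
#'
#' @param z Fixed-effect values (numeric vector).
#' @param posterior A `posterior_u` for the variants' gene.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
uneecon_score <- function(z, posterior) {
  stopifnot(inherits(posterior, "posterior_u"))
  w <- exp(posterior$log_weights)
  1 - drop(stats::plogis(outer(z, posterior$nodes, "+")) %*% w)
}

#' Gene-level constraint score
#'
#' The arithmetic mean of the variant scores over a gene's candidate
#' missense mutations (the variant universe is exactly the set supplied).
#' An empty gene yields `NA` (an explicit missing marker), never 0.
#'
#' @param scores Numeric vector of variant scores for one gene.
#' @return A single probability, or `NA_real_` for an empty gene.
#' @export
uneecon_g <- function(scores) {
  if (!length(scores)) return(NA_real_)
  mean(scores)
}

#' Score variants and genes under a fitted model
#'
#' For every gene batch: standardizes features with the fit's standardizer,
#' computes inference-mode fixed effects, forms the posterior of the gene
#' random effect from the batch's occurrence data (or the prior, when the
#' batch has no occurrence data or `use_prior = TRUE` -- the behaviour used
#' for genes absent from training, where the random effect is replaced by
#' its genome-wide average), and returns per-variant and per-gene scores.
#' Scoring is deterministic: identical inputs give identical outputs.
#'
#' @param fit A `dme_fit` from [train_dme()], or a list with `params` and
#'   `standardizer`.
#' @param batches Named list of [gene_batch()]es (raw feature scale).
#' @param order Quadrature order; defaults to the fit's training order.
#' @param use_prior If TRUE, ignore each gene's occurrence data and use the
#'   prior random effect for all genes.
#' @return List with `variants` (data.frame: key columns, `gene_id`, `z`,
#'   `score`) and `genes` (data.frame: `gene_id`, `n_variants`,
#'   `posterior_mean`, `posterior_sd`, `gene_score`).
#' @export
score_variants <- function(fit, batches, order = NULL, use_prior = FALSE) {
  params <- fit$params
  order <- order %||% (fit$config$quadrature_order %||% 20L)
  var_rows <- list(); gene_rows <- list()
  for (b in batches) {
    Xs <- apply_standardizer(fit$standardizer, b$X)
    sb <- b; sb$X <- Xs
    post <- if (use_prior || is.null(b$Y)) {
      prior_u(params, order, gene_id = b$gene_id)
    } else {
      posterior_u(sb, params, order)
    }
    z <- forward_cache(Xs, params, mode = "infer")$z
    sc <- uneecon_score(z, post)
    keys <- b$keys %||% data.frame(row = seq_along(z))
    var_rows[[b$gene_id]] <- cbind(keys,
                                   data.frame(gene_id = b$gene_id, z = z,
                                              score = sc,
                                              stringsAsFactors = FALSE))
    gene_rows[[b$gene_id]] <- data.frame(
      gene_id = b$gene_id, n_variants = length(z),
      posterior_mean = post$mean, posterior_sd = post$sd,
      gene_score = uneecon_g(sc), stringsAsFactors = FALSE)
  }
  list(variants = do.call(rbind, c(var_rows, list(make.row.names = FALSE))),
       genes = do.call(rbind, c(gene_rows, list(make.row.names = FALSE))))
}

#' Feature contributions from the linear surrogate
#'
#' For the linear model (no hidden layer) the fixed effect is a linear
#' combination of features, so the model reads as a generalized linear
#' mixed model.  The contribution score of a feature is the negative of
#' its weight, and the contribution of the gene-level random effect is the
#' negative of its standard deviation: positive contributions mark
#' variables positively associated with negative selection.
#'
#' @param params A linear [dme_params()] (`hidden_units = 0`), or a
#'   `dme_fit` holding one.
#' @return Data.frame with `term` (feature names plus
#'   `"gene_random_effect"`) and `contribution`.
#' @export
contribution_scores <- function(params) {
  if (inherits(params, "dme_fit")) params <- params$params
  stopifnot(inherits(params, "dme_params"))
  if (params$hidden_units > 0L)
    stop_uneecon("contribution scores are defined for the linear model only; train a linear surrogate (hidden_units = 0) and call this on it")
  data.frame(
    term = c(params$feature_names, "gene_random_effect"),
    contribution = c(-params$W_output, -params$sigma),
    stringsAsFactors = FALSE)
}
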