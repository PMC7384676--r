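## Deep mixed-effects model parameters ----------------------------------------

#' Construct (and initialize) DME parameters
#'
#' Holds the fixed-effect network weights and the random-effect standard
#' deviation.  With `hidden_units = 0` the model is linear (a generalized
#' linear mixed model): `W_output` acts directly on the features and the
#' hidden layer is absent.  Weights are initialized with Glorot uniform
#' draws, biases with zeros, and `sigma` at 0.5 (optimized on the log scale
#' during training).
#'
#' @param n_features Number of input features.
#' @param hidden_units Hidden layer width; 0 for the linear model.
#' @param sigma Initial random-effect standard deviation (> 0).
#' @param dropout_rate Dropout rate applied to the hidden layer during
#'   training (default 0.5; ignored for the linear model).
#' @param feature_names Optional character vector of feature names.
#' @param seed Optional seed for the Glorot draws.
#' @return A `dme_params` object with elements `W_hidden`, `B_hidden`
#'   (NULL when linear), `W_output`, `b_output`, `sigma`, `hidden_units`,
#'   `dropout_rate`, `feature_names`.
#' @export
dme_params <- function(n_features, hidden_units = 0L, sigma = 0.5,
                       dropout_rate = 0.5, feature_names = NULL,
                       seed = NULL) {
  if (!is_count(n_features)) stop_uneecon("`n_features` must be a positive integer")
  if (sigma <= 0) stop_uneecon("`sigma` must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_uneecon("`dropout_rate` must be in [0, 1)")
  hidden_units <- as.integer(hidden_units)
  glorot <- function(fan_in, fan_out, n) {
    lim <- sqrt(6 / (fan_in + fan_out))
    stats::runif(n, -lim, lim)
  }
  p <- with_seed_or_not(seed, {
    if (hidden_units > 0L) {
      list(
        W_hidden = matrix(glorot(n_features, hidden_units,
                                 n_features * hidden_units),
                          n_features, hidden_units),
        B_hidden = numeric(hidden_units),
        W_output = glorot(hidden_units, 1L, hidden_units),
        b_output = 0
      )
    } else {
      list(W_hidden = NULL, B_hidden = NULL,
           W_output = glorot(n_features, 1L, n_features),
           b_output = 0)
    }
  })
  p$sigma <- sigma
  p$hidden_units <- hidden_units
  p$dropout_rate <- dropout_rate
  p$feature_names <- feature_names %||% paste0("feature_", seq_len(n_features))
  p$n_features <- as.integer(n_features)
  structure(p, class = "dme_params")
}

validate_dme_params <- function(params, n_features) {
  stopifnot(inherits(params, "dme_params"))
  if (params$n_features != n_features)
    stop_uneecon("feature count mismatch: params expect %d, data has %d",
                 params$n_features, n_features)
  if (params$hidden_units > 0L) {
    stopifnot(nrow(params$W_hidden) == n_features,
              ncol(params$W_hidden) == params$hidden_units,
              length(params$W_output) == params$hidden_units)
  } else {
    stopifnot(length(params$W_output) == n_features)
  }
  if (params$sigma <= 0) stop_uneecon("sigma must be positive")
  invisible(params)
}

#' @export
print.dme_params <- function(x, ...) {
  cat(sprintf(
    "Deep mixed-effects model parameters: %s, %d feature(s), sigma = %.4f\n",
    if (x$hidden_units > 0L) sprintf("%d hidden units", x$hidden_units)
    else "linear (no hidden layer)",
    x$n_features, x$sigma))
  invisible(x)
}

#' Assemble per-gene minibatches
#'
#' Splits a variant table into the per-gene batches the trainer and scorer
#' consume: feature matrix `X`, neutral probabilities `mu`, occurrence
#' indicators `Y`, plus the variant key columns for reporting.
#'
#' @param variants Variant table with feature columns.
#' @param mu Numeric vector of neutral occurrence probabilities aligned
#'   with the rows (all strictly in (0, 1)), e.g. `compute_mu()$mu`.
#' @param feature_columns Character vector naming the feature columns;
#'   defaults to `attr(variants, "feature_columns")`.
#' @return Named list of `gene_batch` objects (one per gene, in order of
#'   first appearance), each with `gene_id`, `X`, `mu`, `Y`, `keys`.
#' @export
make_gene_batches <- function(variants, mu, feature_columns = NULL) {
  feature_columns <- feature_columns %||% attr(variants, "feature_columns")
  if (is.null(feature_columns) || !length(feature_columns))
    stop_uneecon("no feature columns found; pass `feature_columns`")
  if (length(mu) != nrow(variants))
    stop_uneecon("`mu` length does not match variant rows")
  if (any(mu <= 0 | mu >= 1))
    stop_uneecon("all `mu` must lie strictly in (0, 1)")
  X <- as.matrix(variants[, feature_columns, drop = FALSE])
  genes <- unique(variants$gene_id)
  batches <- lapply(genes, function(g) {
    rows <- which(variants$gene_id == g)
    gene_batch(g, X[rows, , drop = FALSE], mu[rows],
               variants$observed[rows],
               keys = variants[rows, intersect(c("chrom", "pos", "ref", "alt"),
                                               names(variants)), drop = FALSE])
  })
  stats::setNames(batches, genes)
}

#' Construct a single gene batch
#'
#' @param gene_id Gene identifier.
#' @param X Feature matrix (variants x features).
#' @param mu Neutral occurrence probabilities, strictly in (0, 1).
#' @param Y Binary occurrence indicators (may be NULL for scoring a gene
#'   without occurrence data, in which case the prior random effect is
#'   used).
#' @param keys Optional data.frame of variant identifiers.
#' @return A `gene_batch` object.
#' @export
gene_batch <- function(gene_id, X, mu, Y = NULL, keys = NULL) {
  X <- as.matrix(X)
  if (length(mu) != nrow(X))
    stop_uneecon("gene %s: mu length %d != %d variants", gene_id,
                 length(mu), nrow(X))
  if (any(mu <= 0 | mu >= 1))
    stop_uneecon("gene %s: all mu must lie strictly in (0, 1)", gene_id)
  if (!is.null(Y)) {
    if (length(Y) != nrow(X))
      stop_uneecon("gene %s: Y length mismatch", gene_id)
    if (!all(Y %in% c(0, 1)))
      stop_uneecon("gene %s: Y must be binary", gene_id)
  }
  structure(list(gene_id = as.character(gene_id), X = X,
                 mu = as.numeric(mu), Y = if (is.null(Y)) NULL else as.numeric(Y),
                 keys = keys),
            class = "gene_batch")
}
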