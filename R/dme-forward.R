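## Fixed-effect network -------------------------------------------------------

#' Standardize feature columns
#'
#' Continuous columns are centred on their mean and scaled by their
#' population (denominator-`n`) standard deviation; binary columns are left
#' untouched.  The returned standardizer is reused verbatim at scoring
#' time so training and scoring see identical transforms.
#'
#' @param X Numeric feature matrix.
#' @param feature_kinds Optional character vector (`"continuous"` or
#'   `"binary"`) per column; by default a column whose values all lie in
#'   {0, 1} is treated as binary.
#' @return List with `X` (standardized matrix) and `standardizer` (a
#'   `feature_standardizer`: per-column `center`, `scale`, `kind`).
#' @export
standardize_features <- function(X, feature_kinds = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(feature_kinds)) {
    feature_kinds <- unname(ifelse(
      apply(X, 2L, function(v) all(v %in% c(0, 1))), "binary", "continuous"))
  }
  if (length(feature_kinds) != p)
    stop_uneecon("`feature_kinds` length %d != %d columns",
                 length(feature_kinds), p)
  if (!all(feature_kinds %in% c("continuous", "binary")))
    stop_uneecon("`feature_kinds` entries must be 'continuous' or 'binary'")
  center <- numeric(p); scale <- rep(1, p)
  cont <- feature_kinds == "continuous"
  if (any(cont)) {
    center[cont] <- colMeans(X[, cont, drop = FALSE])
    n <- nrow(X)
    scale[cont] <- sqrt(colMeans(X[, cont, drop = FALSE]^2) - center[cont]^2)
    zero <- cont & (scale == 0 | !is.finite(scale))
    if (any(zero)) {
      nm <- colnames(X) %||% paste0("column ", seq_len(p))
      stop_uneecon("zero-variance continuous feature column(s): %s",
                   paste(nm[zero], collapse = ", "))
    }
  }
  std <- structure(list(center = center, scale = scale, kind = feature_kinds,
                        colnames = colnames(X)),
                   class = "feature_standardizer")
  list(X = apply_standardizer(std, X), standardizer = std)
}

#' Apply a fitted feature standardizer
#'
#' @param standardizer A `feature_standardizer` from [standardize_features()].
#' @param X Feature matrix with the same columns as the fitting set.
#' @return Standardized matrix.
#' @export
apply_standardizer <- function(standardizer, X) {
  stopifnot(inherits(standardizer, "feature_standardizer"))
  X <- as.matrix(X)
  if (ncol(X) != length(standardizer$center))
    stop_uneecon("standardizer expects %d columns, got %d",
                 length(standardizer$center), ncol(X))
  sweep(sweep(X, 2L, standardizer$center, "-"), 2L, standardizer$scale, "/")
}

#' Fixed-effect forward pass
#'
#' Computes the variant-level fixed effect `z` from standardized features.
#' With hidden units the layer is `H = dropout(ReLU(X W_hidden + B_hidden))`
#' followed by `z = H W_output + b_output`; the linear model bypasses the
#' hidden layer (`H = X`).  Dropout is inverted (surviving activations are
#' scaled by `1 / (1 - rate)`) and active only in `"train"` mode;
#' `"infer"` mode is fully deterministic.
#'
#' @param X_std Standardized feature matrix.
#' @param params A `dme_params`.
#' @param mode `"infer"` (default, deterministic) or `"train"` (dropout
#'   mask sampled from the current RNG stream, or from `seed` if given).
#' @param seed Optional seed for the dropout mask.
#' @return Numeric vector `z` of length `nrow(X_std)`.
#' @export
forward_fixed_effect <- function(X_std, params, mode = c("infer", "train"),
                                 seed = NULL) {
  mode <- match.arg(mode)
  forward_cache(X_std, params, mode = mode, seed = seed)$z
}

## Forward pass retaining intermediates for backpropagation.
forward_cache <- function(X_std, params, mode = "infer", seed = NULL) {
  X_std <- as.matrix(X_std)
  validate_dme_params(params, ncol(X_std))
  if (params$hidden_units == 0L) {
    z <- drop(X_std %*% params$W_output) + params$b_output
    return(list(z = z, H = X_std, pre = NULL, mask = NULL))
  }
  pre <- sweep(X_std %*% params$W_hidden, 2L, params$B_hidden, "+")
  H <- pmax(pre, 0)
  mask <- NULL
  if (mode == "train" && params$dropout_rate > 0) {
    keep <- 1 - params$dropout_rate
    mask <- with_seed_or_not(seed,
      matrix(stats::rbinom(length(H), 1L, keep), nrow(H), ncol(H)))
    H <- H * mask / keep
  }
  z <- drop(H %*% params$W_output) + params$b_output
  list(z = z, H = H, pre = pre, mask = mask)
}

#' Relative occurrence probability under selection
#'
#' `eta = logistic(z + u)`: the probability of observing a mutation
#' relative to the neutral expectation, given the fixed effect `z` and the
#' gene random effect `u`.  Strictly inside (0, 1) and monotone in `z + u`.
#'
#' @param z,u Numeric vectors (recycled).
#' @return Numeric vector of probabilities.
#' @export
eta <- function(z, u) logistic(z + u)
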