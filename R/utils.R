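#' Logistic (inverse-logit) and logit transforms
#'
#' Thin wrappers over [stats::plogis()] and [stats::qlogis()], kept as named
#' functions because the logit scale is the package's working scale.
#'
#' @param x Numeric vector.
#' @param p Numeric vector of probabilities in (0, 1).
#' @return Numeric vector.
#' @export
logistic <- function(x) stats::plogis(x)

#' @rdname logistic
#' @export
logit <- function(p) stats::qlogis(p)

#' Numerically stable log-sum-exp
#'
#' @param x Numeric vector (may contain -Inf).
#' @return `log(sum(exp(x)))` computed without overflow.
#' @export
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under `seed` without disturbing the caller's RNG stream;
## seed = NULL runs in the ambient stream (used inside seeded loops).
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

stop_uneecon <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x >= 1
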