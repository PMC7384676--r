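#' Gauss-Hermite rule for integrals against a centered Gaussian
#'
#' Returns nodes and log-weights such that for a function `g`,
#' `integral g(u) N(u; 0, sigma) du ~= sum(exp(log_w) * g(u))`.
#' Uses the physicists' Gauss-Hermite rule with the change of variables
#' `u = sqrt(2) * sigma * x`, which folds the Gaussian density into the
#' rule's weight function; weights are returned on the log scale because
#' gene likelihoods are accumulated with log-sum-exp.
#'
#' @param sigma Positive standard deviation of the Gaussian.
#' @param order Number of quadrature nodes (>= 2).
#' @return List with `u` (nodes on the random-effect scale) and `log_w`
#'   (log weights summing to ~0 on the log scale, i.e. `sum(exp(log_w)) = 1`).
#' @export
#' @examples
#' r <- gauss_hermite_gaussian(sigma = 1, order = 20)
#' sum(exp(r$log_w))            # 1
#' sum(exp(r$log_w) * r$u^2)    # sigma^2
gauss_hermite_gaussian <- function(sigma, order = 20L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop_uneecon("`sigma` must be a single positive number, got %s",
                 format(sigma))
  rule <- gh_rule(order)
  list(u = sqrt(2) * sigma * rule$x,
       log_w = log(rule$w) - 0.5 * log(pi))
}

## Cache raw Hermite nodes/weights per order; pracma recomputes via Newton
## iterations which is wasteful inside training loops.
gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(order) {
  if (!is_count(order) || order < 2)
    stop_uneecon("quadrature `order` must be an integer >= 2, got %s",
                 format(order))
  key <- as.character(as.integer(order))
  if (is.null(gh_cache[[key]]))
    gh_cache[[key]] <- pracma::gaussHermite(as.integer(order))
  gh_cache[[key]]
}
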