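## Marginal likelihood and gradients ------------------------------------------
##
## For gene j with variants i, the per-gene likelihood is
##   L_j = integral prod_i (eta_ij mu_ij)^Y_ij (1 - eta_ij mu_ij)^(1 - Y_ij)
##         N(u; 0, sigma) du,        eta_ij = logistic(z_ij + u).
## The integral is evaluated by Gauss-Hermite quadrature on the nodes
## u_k = sqrt(2) sigma x_k and accumulated with log-sum-exp.  Gradients with
## respect to z (and hence the network weights, by backpropagation) and
## log(sigma) reuse the normalized node responsibilities r_k.

## Per-node joint log-likelihood S_k = sum_i log p_i(u_k); optionally the
## per-variant score matrix G[i, k] = d log p_i / d (z_i + u) at node k.
gene_ll_nodes <- function(z, mu, Y, u_nodes, want_grad = FALSE) {
  ZU <- outer(z, u_nodes, "+")
  log_eta <- stats::plogis(ZU, log.p = TRUE)
  eta_m <- stats::plogis(ZU)
  obs <- Y == 1                       # mu and Y recycle down columns (variants)
  lp <- log1p(-eta_m * mu)
  lp[obs, ] <- log(mu[obs]) + log_eta[obs, , drop = FALSE]
  out <- list(S = colSums(lp))
  if (want_grad) {
    G <- -(mu * eta_m * (1 - eta_m)) / (1 - eta_m * mu)
    G[obs, ] <- 1 - eta_m[obs, , drop = FALSE]
    out$G <- G
  }
  out
}

#' Log marginal likelihood of one gene
#'
#' Integrates the gene-level Gaussian random effect out of the Bernoulli
#' likelihood by Gauss-Hermite quadrature (see [gauss_hermite_gaussian()]),
#' accumulating on the log scale.  The feature matrix is taken as already
#' being on the model's scale (standardize with the fit's standardizer).
#'
#' @param batch A [gene_batch()] with occurrence indicators `Y`.
#' @param params A [dme_params()].
#' @param order Quadrature order (default 20).
#' @return A finite scalar: `log L_j`.
#' @export
gene_log_marginal_likelihood <- function(batch, params, order = 20L) {
  stopifnot(inherits(batch, "gene_batch"))
  if (is.null(batch$Y))
    stop_uneecon("gene %s has no occurrence indicators", batch$gene_id)
  z <- forward_cache(batch$X, params, mode = "infer")$z
  gene_logml_z(z, batch$mu, batch$Y, params$sigma, order)
}

gene_logml_z <- function(z, mu, Y, sigma, order) {
  gh <- gauss_hermite_gaussian(sigma, order)
  ll <- gene_ll_nodes(z, mu, Y, gh$u)
  logsumexp(gh$log_w + ll$S)
}

## Negative log marginal likelihood and its gradients for one gene, in
## training mode (dropout active when params carry a positive rate).
## Returns list(nll, grads) with grads named like the trainable arrays.
gene_nll_grad <- function(batch, params, order, mode = "train") {
  fc <- forward_cache(batch$X, params, mode = mode)
  gh <- gauss_hermite_gaussian(params$sigma, order)
  ll <- gene_ll_nodes(fc$z, batch$mu, batch$Y, gh$u, want_grad = TRUE)
  a <- gh$log_w + ll$S
  logml <- logsumexp(a)
  r <- exp(a - logml)                       # node responsibilities
  dz <- drop(ll$G %*% r)                    # d logL / d z_i
  dlogsigma <- sum(r * gh$u * colSums(ll$G))
  grads <- list(b_output = -sum(dz), log_sigma = -dlogsigma)
  if (params$hidden_units == 0L) {
    grads$W_output <- -drop(crossprod(fc$H, dz))
  } else {
    grads$W_output <- -drop(crossprod(fc$H, dz))
    dH <- outer(dz, params$W_output)
    if (!is.null(fc$mask))
      dH <- dH * fc$mask / (1 - params$dropout_rate)
    dpre <- dH * (fc$pre > 0)
    grads$W_hidden <- -crossprod(batch$X, dpre)
    grads$B_hidden <- -colSums(dpre)
  }
  list(nll = -logml, grads = grads)
}
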