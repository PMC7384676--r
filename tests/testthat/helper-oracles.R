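# Independent oracles used across test files.  These deliberately avoid the
# package's own quadrature/likelihood code paths: dense-grid integration and
# naive arithmetic only.

# Dense-trapezoid log marginal likelihood over u in [-10 sigma, 10 sigma].
dense_logml <- function(z, mu, Y, sigma, n_grid = 20001) {
  u <- seq(-10 * sigma, 10 * sigma, length.out = n_grid)
  lp <- vapply(u, function(uu) {
    p <- plogis(z + uu) * mu
    sum(ifelse(Y == 1, log(p), log1p(-p))) + dnorm(uu, 0, sigma, log = TRUE)
  }, 0)
  du <- u[2] - u[1]
  m <- max(lp)
  log(sum(exp(lp - m)) * du) + m
}

# Dense-grid posterior moments of u given the gene data (Bayes rule on a
# grid; no quadrature involved).
dense_posterior <- function(z, mu, Y, sigma, n_grid = 20001) {
  u <- seq(-10 * sigma, 10 * sigma, length.out = n_grid)
  lp <- vapply(u, function(uu) {
    p <- plogis(z + uu) * mu
    sum(ifelse(Y == 1, log(p), log1p(-p))) + dnorm(uu, 0, sigma, log = TRUE)
  }, 0)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  m <- sum(w * u)
  list(mean = m, sd = sqrt(sum(w * u^2) - m^2))
}

# O(n^2) pairwise AUC with ties counted 0.5.
pairwise_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Single-gene batch with scalar feature and identity fixed effect, so z is
# supplied directly.
z_batch <- function(z, mu, Y, gene_id = "g") {
  gene_batch(gene_id, matrix(z, ncol = 1), mu, Y)
}

identity_params <- function(sigma) {
  p <- dme_params(1, hidden_units = 0L, sigma = sigma)
  p$W_output <- 1
  p$b_output <- 0
  p
}

# Small deterministic variant table used by IO tests.
tiny_variant_table <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(101L, 205L, 77L),
    ref = c("A", "C", "G"),
    alt = c("G", "T", "A"),
    gene_id = c("gene_a", "gene_a", "gene_b"),
    exon_id = c("exon_1", "exon_1", "exon_2"),
    context7 = c("TTTAGGG", "ACGCGTA", "AAAGTTT"),
    depth = c(31.5, 28.0, 40.2),
    observed = c(1L, 0L, 0L),
    consequence = c("missense", "missense", "synonymous"),
    feature_1 = c(0.2, -1.1, 0.5),
    feature_2 = c(1.0, 0.0, -0.3),
    stringsAsFactors = FALSE
  )
}
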