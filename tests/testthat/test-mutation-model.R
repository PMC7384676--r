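# Direct simulation from the occurrence regression, bypassing the genome
# machinery: contexts are class labels drawn from a small mutability table.
sim_occurrence <- function(n, alpha0, alpha1, alpha2, n_classes = 20,
                           seed = 1) {
  withr::with_seed(seed, {
    ctx <- paste0("AAA", sample(c("A", "C", "G", "T"), n_classes,
                                replace = TRUE), "AAA")
    # distinct 7-mers: append index via flanks
    ctx <- vapply(seq_len(n_classes), function(i) {
      flank <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                     collapse = "")
      paste0(flank, substr(ctx[i], 4, 4), "AAA")
    }, "")
    ref <- substr(ctx, 4, 4)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    tab <- data.frame(context7 = ctx, alt = alt,
                      count_total = 0L, count_observed = 0L,
                      F = rnorm(n_classes, -2.5, 1))
    tab$f <- plogis(tab$F)
    class(tab) <- c("mutability_table", "data.frame")
    cls <- sample.int(n_classes, n, replace = TRUE)
    depth <- rlnorm(n, log(30), 0.3)
    p <- plogis(alpha0 + alpha1 * log(depth) + alpha2 * tab$F[cls])
    df <- data.frame(chrom = "c1", pos = seq_len(n), ref = ref[cls],
                     alt = alt[cls], gene_id = ".", exon_id = ".",
                     context7 = ctx[cls], depth = depth,
                     observed = rbinom(n, 1, p), consequence = "noncoding",
                     stringsAsFactors = FALSE)
    list(variants = df, mutability = tab)
  })
}

test_that("mutability follows the smoothed proportion formula", {
  df <- data.frame(context7 = rep("AAACAAA", 10), alt = "T",
                   observed = c(rep(1, 3), rep(0, 7)))
  raw <- compute_mutability(df, pseudocount = 0)
  expect_equal(raw$f, 0.3)
  expect_equal(raw$F, log(3 / 7))

  none <- data.frame(context7 = rep("AAACAAA", 10), alt = "T", observed = 0)
  sm <- compute_mutability(none, pseudocount = 0.5)
  expect_equal(sm$f, 0.5 / 11)

  # conservation: observed counts sum to the number of observed variants
  sim <- sim_occurrence(2000, -2, 0.3, 1, seed = 4)
  tab <- compute_mutability(sim$variants)
  expect_equal(sum(tab$count_observed), sum(sim$variants$observed))
  expect_equal(sum(tab$count_total), nrow(sim$variants))
})

test_that("missing mutability classes error instead of defaulting", {
  tab <- compute_mutability(
    data.frame(context7 = "AAACAAA", alt = "T", observed = 1))
  expect_error(lookup_mutability(tab, "TTTGTTT", "A"), "missing")
  # unsmoothed table with f = 1 yields infinite logit: explicit error
  expect_error(
    lookup_mutability(compute_mutability(
      data.frame(context7 = "AAACAAA", alt = "T", observed = 1),
      pseudocount = 0), "AAACAAA", "T"),
    "pseudocount")
})

test_that("genome-wide regression recovers its generating coefficients", {
  truth <- c(-3, 0.5, 1)
  sim <- sim_occurrence(2e5, truth[1], truth[2], truth[3], seed = 7)
  fit <- fit_global_wgs(sim$variants, sim$mutability)
  est <- c(fit$alpha0, fit$alpha1, fit$alpha2)
  expect_true(all(abs(est - truth) < 3 * fit$se))
  # MLE score equation: predicted sum equals observed sum
  expect_equal(sum(fitted(fit$fit)), sum(sim$variants$observed),
               tolerance = 1e-8)
})

test_that("a null mutability effect is not spuriously detected", {
  sim <- sim_occurrence(1e5, -3, 0.5, 0, seed = 8)
  fit <- fit_global_wgs(sim$variants, sim$mutability)
  expect_lt(abs(fit$alpha2), 3 * fit$se["alpha2"])
})

test_that("local exon intercepts recover offsets and fall back safely", {
  base <- sim_occurrence(3e4, -3, 0.5, 1, seed = 9)
  a1 <- 0.5; a2 <- 1

  # no local deviation: alpha3 = alpha0
  loc <- fit_local_exon(base$variants, "e1", a1, a2, base$mutability,
                        alpha0 = -3)
  expect_false(loc$fallback)
  expect_lt(abs(loc$alpha3 - (-3)), 3 * loc$se)

  # doubled local rate: offset recovered near log 2
  dbl <- sim_occurrence(3e4, -3 + log(2), 0.5, 1, seed = 10)
  loc2 <- fit_local_exon(dbl$variants, "e2", a1, a2, dbl$mutability,
                         alpha0 = -3)
  expect_lt(abs(loc2$alpha3 - (-3 + log(2))), 3 * loc2$se)

  # all-zero outcomes: divergence caught, global fallback applied
  allzero <- base$variants[1:50, ]
  allzero$observed <- 0
  loc3 <- fit_local_exon(allzero, "e3", a1, a2, base$mutability, alpha0 = -3)
  expect_true(loc3$fallback)
  expect_equal(loc3$alpha3, -3)

  # empty window
  loc4 <- fit_local_exon(base$variants[0, ], "e4", a1, a2, base$mutability,
                         alpha0 = -3)
  expect_true(loc4$fallback)
})

test_that("q is a pure affine combination on the logit scale", {
  tab <- compute_mutability(
    data.frame(context7 = rep("AAACAAA", 4), alt = "T",
               observed = c(1, 1, 0, 0)))  # f = 0.5 -> F = 0
  v <- data.frame(chrom = "c", pos = 1, ref = "C", alt = "T",
                  gene_id = "g", exon_id = "e1", context7 = "AAACAAA",
                  depth = 1, observed = 0, consequence = "missense")
  par <- mutation_model_params(-99, alpha1 = 0, alpha2 = 1,
                               alpha3 = c(e1 = -3))
  expect_equal(compute_q(v, par, tab), -3)

  # depth = 1 makes log(d) = 0: q independent of alpha1
  par2 <- mutation_model_params(-99, alpha1 = 5, alpha2 = 1,
                                alpha3 = c(e1 = -3))
  expect_equal(compute_q(v, par2, tab), -3)

  # random draws match an independent re-evaluation
  withr::with_seed(3, {
    for (i in 1:10) {
      a1 <- rnorm(1); a2 <- rnorm(1); a3 <- rnorm(1); d <- runif(1, 1, 60)
      vv <- v; vv$depth <- d
      p <- mutation_model_params(0, a1, a2, c(e1 = a3))
      expect_equal(compute_q(vv, p, tab), a3 + a1 * log(d),
                   tolerance = 1e-12)
    }
  })

  expect_error(compute_q(transform(v, exon_id = "eX"), par, tab),
               "eX")
})

test_that("exome recalibration matches closed forms and balances counts", {
  n <- 4000
  v <- data.frame(chrom = "c", pos = seq_len(n), ref = "C", alt = "T",
                  gene_id = "g", exon_id = "e", context7 = "AAACAAA",
                  depth = 30, observed = rep(c(1, 0), n / 2),
                  consequence = "synonymous")
  r <- recalibrate_exome(v, q = rep(0, n))
  expect_equal(r$beta0, 0, tolerance = 1e-9)

  v$observed <- rep(c(1, 0, 0, 0), n / 4)
  r <- recalibrate_exome(v, q = rep(0, n))
  expect_equal(r$beta0, qlogis(0.25), tolerance = 1e-9)

  # simulated offset recovery and exact count conservation
  withr::with_seed(12, {
    q <- rnorm(n, -3, 1)
    v$observed <- rbinom(n, 1, plogis(-1.5 + q))
  })
  r <- recalibrate_exome(v, q)
  expect_lt(abs(r$beta0 - (-1.5)), 3 * r$se)
  expect_equal(sum(plogis(r$beta0 + q)), sum(v$observed), tolerance = 1e-8)
})

test_that("mu is the recalibrated logistic and is monotone in q", {
  tab <- compute_mutability(
    data.frame(context7 = rep("AAACAAA", 4), alt = "T",
               observed = c(1, 1, 0, 0)))
  v <- data.frame(chrom = "c", pos = 1, ref = "C", alt = "T",
                  gene_id = "g", exon_id = "e1", context7 = "AAACAAA",
                  depth = 1, observed = 0, consequence = "missense")
  par0 <- mutation_model_params(0, 0, 1, c(e1 = 0), beta0 = 0)
  expect_equal(compute_mu(v, par0, tab)$mu, 0.5)

  par1 <- mutation_model_params(0, 0, 1, c(e1 = -2), beta0 = -2)
  expect_equal(compute_mu(v, par1, tab)$mu, plogis(-4))

  q_grid <- seq(-6, 2, by = 0.5)
  mu_grid <- plogis(-1 + q_grid)
  expect_true(all(diff(mu_grid) > 0))

  parNA <- mutation_model_params(0, 0, 1, c(e1 = 0))
  expect_error(compute_mu(v, parNA, tab), "beta0")
})
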