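test_that("a gene without evidence recovers the prior random effect", {
  p <- identity_params(0.9)
  empty <- gene_batch("g0", matrix(numeric(0), 0, 1), numeric(0), numeric(0))
  post <- posterior_u(empty, p, 20)
  expect_equal(post$mean, 0, tolerance = 1e-12)
  expect_equal(post$sd, 0.9, tolerance = 1e-10)
  expect_equal(sum(exp(post$log_weights)), 1, tolerance = 1e-12)
})

test_that("posterior moments match a dense-grid Bayes oracle", {
  withr::with_seed(19, {
    for (i in 1:10) {
      n <- sample(3:10, 1)
      z <- rnorm(n); mu <- runif(n, 0.05, 0.4); Y <- rbinom(n, 1, 0.3)
      post <- posterior_u(z_batch(z, mu, Y), identity_params(1), 20)
      want <- dense_posterior(z, mu, Y, 1)
      expect_equal(post$mean, want$mean, tolerance = 1e-4)
      expect_equal(post$sd, want$sd, tolerance = 1e-4)
    }
  })

  # strong depletion pulls the posterior mean negative
  depl <- z_batch(rep(1, 30), rep(0.4, 30), rep(0, 30))
  post <- posterior_u(depl, identity_params(1), 20)
  expect_lt(post$mean, 0)
  expect_lt(abs(post$mean - dense_posterior(rep(1, 30), rep(0.4, 30),
                                            rep(0, 30), 1)$mean), 1e-4)
})

test_that("variant scores are posterior-averaged logistic complements", {
  p <- identity_params(1)
  prior <- uneecon:::prior_u(p, 20)

  # z = 0 under a symmetric posterior scores exactly 0.5
  expect_equal(uneecon_score(0, prior), 0.5, tolerance = 1e-12)
  # logistic limits
  expect_lt(uneecon_score(30, prior), 1e-9)
  expect_gt(uneecon_score(-30, prior), 1 - 1e-9)
  # monotone decreasing in z
  s <- uneecon_score(seq(-4, 4, by = 0.25), prior)
  expect_true(all(diff(s) < 0))
  expect_true(all(s >= 0 & s <= 1))

  # matches the direct weighted sum
  withr::with_seed(29, z <- rnorm(20))
  direct <- 1 - sapply(z, function(zz)
    sum(exp(prior$log_weights) * plogis(zz + prior$nodes)))
  expect_equal(uneecon_score(z, prior), direct, tolerance = 1e-12)
})

test_that("gene scores are plain averages with an explicit empty marker", {
  expect_equal(uneecon_g(c(0.2, 0.2, 0.2)), 0.2)
  expect_equal(uneecon_g(c(0, 1)), 0.5)
  expect_true(is.na(uneecon_g(numeric(0))))
  withr::with_seed(2, s <- runif(1000))
  expect_equal(uneecon_g(s), mean(s))
})

test_that("contribution scores flip signs of linear weights and sigma", {
  p <- dme_params(2, hidden_units = 0, sigma = 0.8,
                  feature_names = c("f1", "f2"))
  p$W_output <- c(0.3, -1.2)
  cs <- contribution_scores(p)
  expect_equal(cs$contribution, c(-0.3, 1.2, -0.8))
  expect_equal(cs$term, c("f1", "f2", "gene_random_effect"))

  pn <- dme_params(2, hidden_units = 8, seed = 1)
  expect_error(contribution_scores(pn), "linear")
})

test_that("scoring is deterministic and bounded on a trained fixture", {
  sim <- simulate_missense_dataset(n_genes = 20, variants_per_gene = 30,
                                   n_features = 3, sigma_true = 1, seed = 13)
  fit <- train_dme(sim$batches,
                   train_config(max_epochs = 5, split_fractions = c(1, 0, 0),
                                seed = 13))
  s1 <- score_variants(fit, sim$batches)
  s2 <- score_variants(fit, sim$batches)
  expect_identical(s1, s2)
  expect_true(all(s1$variants$score >= 0 & s1$variants$score <= 1))
  expect_true(all(s1$genes$gene_score >= 0 & s1$genes$gene_score <= 1))
  # gene score equals the mean of its variants' scores
  for (g in s1$genes$gene_id[1:5]) {
    expect_equal(s1$genes$gene_score[s1$genes$gene_id == g],
                 mean(s1$variants$score[s1$variants$gene_id == g]),
                 tolerance = 1e-12)
  }
})

test_that("leave-gene-out scoring equals the forced-prior computation", {
  sim <- simulate_missense_dataset(n_genes = 12, variants_per_gene = 25,
                                   n_features = 3, sigma_true = 1, seed = 14)
  fit <- train_dme(sim$batches[1:10],
                   train_config(max_epochs = 5, split_fractions = c(1, 0, 0),
                                seed = 14))
  held_out <- sim$batches[11:12]
  forced <- score_variants(fit, held_out, use_prior = TRUE)
  no_y <- lapply(held_out, function(b) { b$Y <- NULL; b })
  implied <- score_variants(fit, no_y)
  expect_equal(implied$variants$score, forced$variants$score,
               tolerance = 1e-12)
  expect_equal(implied$genes$posterior_mean, forced$genes$posterior_mean)
})

test_that("a depleted gene outranks an identically featured tolerant gene", {
  withr::with_seed(55, {
    X <- matrix(rnorm(40 * 2), 40, 2)
    mu <- runif(40, 0.2, 0.4)
  })
  p <- dme_params(2, hidden_units = 0, sigma = 1.5)
  p$W_output <- c(0.5, -0.5); p$b_output <- 0
  z <- drop(X %*% p$W_output)
  withr::with_seed(56, {
    y_depleted <- rbinom(40, 1, plogis(z - 2) * mu)
    y_tolerant <- rbinom(40, 1, plogis(z + 2) * mu)
  })
  fit <- list(params = p,
              standardizer = standardize_features(X)$standardizer)
  # raw X passes through the standardizer; use the same X for both genes
  res <- score_variants(fit, list(
    gene_batch("depleted", X, mu, y_depleted),
    gene_batch("tolerant", X, mu, y_tolerant)), order = 20)
  gs <- setNames(res$genes$gene_score, res$genes$gene_id)
  expect_gt(gs["depleted"], gs["tolerant"])
})
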