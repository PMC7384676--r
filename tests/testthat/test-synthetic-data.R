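test_that("simulated genomes honour GC content, determinism, and exon packing", {
  sim <- simulate_genome(contig_length = 100000L, gc = 0.5, n_exons = 4,
                         seed = 2)
  comp <- Biostrings::letterFrequency(sim$genome[[1]], c("G", "C"))
  expect_lt(abs(sum(comp) / 100000 - 0.5), 0.02)

  sim2 <- simulate_genome(contig_length = 100000L, gc = 0.5, n_exons = 4,
                          seed = 2)
  expect_identical(as.character(sim$genome[[1]]), as.character(sim2$genome[[1]]))

  ov <- GenomicRanges::findOverlaps(sim$exons, sim$exons)
  expect_equal(length(ov), length(sim$exons))  # self-hits only

  expect_error(simulate_genome(contig_length = 1000L, n_exons = 10,
                               exon_length = 100L), "pack")
})

test_that("neutral occurrence follows the generating logistic model", {
  sim <- simulate_genome(contig_length = 60000L, n_exons = 2, seed = 5)
  mask <- GenomicRanges::GRanges("contig_1", IRanges::IRanges(1, 60000))
  mut <- simulate_mutability_table(sim$genome, seed = 5)

  # intercept-only model: occurrence frequency matches the intercept
  par <- mutation_model_params(qlogis(0.1), 0, 0,
                               setNames(rep(qlogis(0.1), 2),
                                        sim$exons$exon_id))
  nv <- simulate_neutral_variants(sim$genome, mask, par, mut, sim$exons,
                                  n_sites = 50000L, seed = 6)
  expect_lt(abs(mean(nv$observed) - 0.1), 0.005)
  # contexts come from the genome
  g1 <- as.character(sim$genome[[1]])
  idx <- sample.int(nrow(nv), 50)
  expect_equal(substring(g1, nv$pos[idx] - 3, nv$pos[idx] + 3),
               nv$context7[idx])

  # depth effect: doubling depth raises occurrence when alpha1 > 0
  par2 <- mutation_model_params(-2.5, 1.0, 0,
                                setNames(rep(-2.5, 2), sim$exons$exon_id))
  lo <- simulate_neutral_variants(sim$genome, mask, par2, mut, sim$exons,
                                  n_sites = 20000L,
                                  depth_meanlog = log(15), seed = 7)
  hi <- simulate_neutral_variants(sim$genome, mask, par2, mut, sim$exons,
                                  n_sites = 20000L,
                                  depth_meanlog = log(30), seed = 7)
  expect_gt(mean(hi$observed), mean(lo$observed))

  # determinism
  nv2 <- simulate_neutral_variants(sim$genome, mask, par, mut, sim$exons,
                                   n_sites = 1000L, seed = 8)
  nv3 <- simulate_neutral_variants(sim$genome, mask, par, mut, sim$exons,
                                   n_sites = 1000L, seed = 8)
  expect_identical(nv2, nv3)
})

test_that("missense datasets obey their generative probabilities", {
  # null model: P(Y) = logistic(0) * mu = mu / 2; tight mu near 0.5
  sim <- simulate_missense_dataset(n_genes = 100, variants_per_gene = 1000,
                                   n_features = 2, weights = c(0, 0),
                                   bias = 0, sigma_true = 0,
                                   mu_shape = c(5000, 5000), seed = 3)
  y <- unlist(lapply(sim$batches, `[[`, "Y"))
  expect_lt(abs(mean(y) - 0.25), 0.01)

  # gene-level effects separate matched genes
  sim2 <- simulate_missense_dataset(n_genes = 2, variants_per_gene = 4000,
                                    n_features = 2, weights = c(0, 0),
                                    bias = 0, sigma_true = 0,
                                    mu_shape = c(50, 50), seed = 4)
  b_lo <- sim2$batches[[1]]; b_hi <- sim2$batches[[2]]
  withr::with_seed(9, {
    y_lo <- rbinom(4000, 1, plogis(-3) * b_lo$mu)
    y_hi <- rbinom(4000, 1, plogis(3) * b_hi$mu)
  })
  expect_gt(mean(y_hi), mean(y_lo))

  # determinism and recorded truth
  a <- simulate_missense_dataset(n_genes = 5, variants_per_gene = 10,
                                 n_features = 3, sigma_true = 1, seed = 10)
  b <- simulate_missense_dataset(n_genes = 5, variants_per_gene = 10,
                                 n_features = 3, sigma_true = 1, seed = 10)
  expect_identical(lapply(a$batches, `[[`, "Y"), lapply(b$batches, `[[`, "Y"))
  expect_identical(a$truth$u_true, b$truth$u_true)
  expect_equal(length(a$truth$u_true), 5)
})

test_that("labelled benchmarks are balanced and behave at the extremes", {
  withr::with_seed(7, {
    tab <- data.frame(score = c(rnorm(300, 1), rnorm(400, 0)),
                      truth = rep(c(TRUE, FALSE), c(300, 400)))
  })
  bench <- make_labeled_benchmark(tab, n_pos = 100, n_neg = 100, seed = 1)
  expect_equal(nrow(bench), 200)
  expect_equal(sum(bench$label), 100)
  expect_error(make_labeled_benchmark(tab, n_pos = 500, n_neg = 100),
               "insufficient")

  # disjoint supports give AUC 1 downstream
  disj <- data.frame(score = c(rnorm(50) + 100, rnorm(50)),
                     truth = rep(c(TRUE, FALSE), each = 50))
  bb <- make_labeled_benchmark(disj, 30, 30, seed = 2)
  auc <- balanced_auc(bb$score[bb$label == 1], bb$score[bb$label == 0])
  expect_equal(auc$auc, 1)

  # permuted labels give chance-level AUC on average
  withr::with_seed(3, {
    aucs <- replicate(100, {
      perm <- tab
      perm$truth <- sample(perm$truth)
      bb <- make_labeled_benchmark(perm, 50, 50,
                                   seed = sample.int(1e6, 1))
      balanced_auc(bb$score[bb$label == 1], bb$score[bb$label == 0],
                   seed = 1)$auc
    })
  })
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(length(aucs)))
})
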