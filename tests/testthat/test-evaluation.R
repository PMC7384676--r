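test_that("balanced AUC equals the pairwise comparison oracle", {
  expect_equal(balanced_auc(c(3, 4), c(1, 2))$auc, 1)
  expect_equal(balanced_auc(rep(1, 10), rep(1, 10))$auc, 0.5)

  withr::with_seed(15, {
    pos <- sample(round(rnorm(50, 0.5), 1))   # rounded: forces ties
    neg <- sample(round(rnorm(50, 0.0), 1))
  })
  expect_equal(balanced_auc(pos, neg)$auc, pairwise_auc(pos, neg))

  # invariance under a strictly monotone transform
  expect_equal(balanced_auc(exp(pos), exp(neg))$auc,
               balanced_auc(pos, neg)$auc)

  # downsampling is seeded and balanced
  withr::with_seed(16, big <- rnorm(500))
  r <- balanced_auc(pos, big, seed = 3)
  expect_length(r$neg, length(pos))
  expect_identical(r$neg, balanced_auc(pos, big, seed = 3)$neg)

  expect_error(balanced_auc(numeric(0), neg), "nonempty")
})

test_that("percentile enrichment reproduces the direct 2x2 formula", {
  # engineered pooled distribution: cases 30 high/10 low, controls 20/40
  cases <- c(rep(2, 30), rep(0, 10))
  controls <- c(rep(2, 20), rep(0, 40))
  r <- percentile_enrichment(cases, controls, percentile = 50)
  expect_equal(unclass(r$table)[1:4], c(30, 20, 10, 40))
  expect_equal(r$log2_or, log2(6), tolerance = 1e-12)
  expect_equal(r$se_log2_or,
               sqrt(1 / 30 + 1 / 10 + 1 / 20 + 1 / 40) / log(2),
               tolerance = 1e-12)
  expect_false(r$corrected)
  expect_equal(sum(r$table), length(cases) + length(controls))

  # perfect separation triggers the zero-cell correction but stays finite
  sep <- percentile_enrichment(rep(5, 20), rep(1, 80), percentile = 20)
  expect_true(sep$corrected)
  expect_true(is.finite(sep$log2_or))

  # all-equal scores are flagged
  flat <- percentile_enrichment(rep(1, 10), rep(1, 10), percentile = 30)
  expect_true(flat$degenerate)

  expect_error(percentile_enrichment(1:5, 1:5, 0), "percentile")
})

test_that("exchangeable scores centre the log2 odds ratio at zero", {
  withr::with_seed(18, {
    l2 <- replicate(200, {
      pool <- rnorm(200)
      pick <- sample.int(200, 100)
      percentile_enrichment(pool[pick], pool[-pick], 20)$log2_or
    })
  })
  expect_lt(abs(mean(l2)), 3 * sd(l2) / sqrt(length(l2)))
})

test_that("length matching pairs genes better than random sampling", {
  withr::with_seed(25, {
    positives <- data.frame(gene_id = sprintf("p%02d", 1:40),
                            length = round(rlnorm(40, 8, 1)))
    pool <- data.frame(gene_id = sprintf("n%03d", 1:400),
                       length = round(rlnorm(400, 8, 1)))
  })
  m <- match_negatives_by_length(positives, pool, seed = 1)
  expect_equal(nrow(m), nrow(positives))
  expect_equal(anyDuplicated(m$gene_id), 0L)

  # exact duplicates in the pool give a perfect match
  dup_pool <- rbind(pool,
                    data.frame(gene_id = paste0("d", 1:40),
                               length = positives$length))
  md <- match_negatives_by_length(positives, dup_pool, seed = 1)
  expect_equal(sort(md$length), sort(positives$length))

  matched_err <- mean(abs(log(m$length) - log(positives$length)))
  withr::with_seed(26, {
    rand_err <- mean(replicate(100, {
      r <- pool[sample.int(nrow(pool), nrow(positives)), ]
      mean(abs(log(r$length) - log(positives$length)))
    }))
  })
  expect_lt(matched_err, rand_err)

  expect_error(match_negatives_by_length(pool, positives), "smaller")
})

test_that("median splits are deterministic, tie-stable, and sized correctly", {
  withr::with_seed(27, s <- setNames(runif(1912), sprintf("g%04d", 1:1912)))
  sp <- median_split(s)
  expect_length(sp$upper, 956)
  expect_length(sp$lower, 956)
  expect_gte(min(s[sp$upper]), max(s[sp$lower]))

  two <- median_split(c(a = 0.1, b = 0.9))
  expect_equal(two$upper, "b")
  expect_equal(two$lower, "a")

  # odd n: upper half gets the extra gene
  odd <- median_split(setNames(runif(7), letters[1:7]))
  expect_length(odd$upper, 4)

  tied <- setNames(rep(0.5, 6), c("f", "a", "d", "b", "e", "c"))
  t1 <- median_split(tied)
  expect_equal(t1$upper, c("a", "b", "c"))
  expect_identical(t1, median_split(tied[sample(6)]))
})
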