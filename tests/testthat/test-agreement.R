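test_that("paired ratings validate their inputs", {
  expect_error(paired_ratings(1:3, 1:4), "equal length")
  expect_error(paired_ratings(c(1, NA, 3), 1:3), "NA")
  r <- paired_ratings(1:5, 2:6)
  expect_identical(r$n, 5L)
})

test_that("perfect and offset agreement give ICC of one", {
  x <- c(5.5, 4.75, 4.0, 3.5, 3.25, 3.0)
  res <- icc_consistency_k(paired_ratings(x, x))
  expect_equal(res$icc, 1)
  # consistency-type agreement ignores a fixed shift
  res2 <- icc_consistency_k(paired_ratings(x, x + 0.75))
  expect_equal(res2$icc, 1)
  expect_error(icc_consistency_k(paired_ratings(1:2, 2:3)), "at least 3")
  expect_warning(icc_consistency_k(paired_ratings(rep(1, 4), rep(1, 4))),
                 "undefined")
})

test_that("ICC matches an independent two-way ANOVA computed with aov", {
  m1 <- c(5.50, 4.75, 4.25, 4.00, 3.75, 3.25)
  m2 <- c(5.25, 5.00, 4.00, 4.25, 3.50, 3.25)
  res <- icc_consistency_k(paired_ratings(m1, m2))
  df <- data.frame(y = c(m1, m2),
                   subject = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  expect_equal(res$icc, (msr - mse) / msr, tolerance = 1e-10)
  # the F-based confidence bounds from the same mean squares
  fobs <- msr / mse
  lo <- 1 - 1 / (fobs / stats::qf(0.975, 5, 5))
  hi <- 1 - 1 / (fobs * stats::qf(0.975, 5, 5))
  expect_equal(res$ci_low, lo, tolerance = 1e-10)
  expect_equal(res$ci_high, hi, tolerance = 1e-10)
  expect_lte(res$ci_low, res$icc)
  expect_lte(res$icc, res$ci_high)
})

test_that("ICC is invariant to a common affine rescaling", {
  set.seed(1)
  m1 <- stats::rnorm(12, 4, 1)
  m2 <- m1 + stats::rnorm(12, 0, 0.3)
  a <- icc_consistency_k(paired_ratings(m1, m2))$icc
  b <- icc_consistency_k(paired_ratings(2.5 * m1 - 3, 2.5 * m2 - 3))$icc
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("estimated ICC recovers the variance-component truth at large n", {
  set.seed(99)
  n <- 1000
  sigma_b <- 1
  sigma_e <- 0.6
  truth <- sigma_b^2 / (sigma_b^2 + sigma_e^2 / 2)
  subj <- stats::rnorm(n, 0, sigma_b)
  m1 <- subj + stats::rnorm(n, 0, sigma_e)
  m2 <- subj + stats::rnorm(n, 0, sigma_e)
  est <- icc_consistency_k(paired_ratings(m1, m2))$icc
  expect_equal(est, truth, tolerance = 0.02)
})

test_that("the 95% CI covers the true ICC about 95% of the time", {
  set.seed(7)
  n <- 25
  sigma_b <- 1
  sigma_e <- 0.5
  truth <- sigma_b^2 / (sigma_b^2 + sigma_e^2 / 2)
  hits <- 0L
  n_sim <- 500L
  for (i in seq_len(n_sim)) {
    subj <- stats::rnorm(n, 0, sigma_b)
    rater_off <- stats::rnorm(2, 0, 0.2)
    m1 <- subj + rater_off[1] + stats::rnorm(n, 0, sigma_e)
    m2 <- subj + rater_off[2] + stats::rnorm(n, 0, sigma_e)
    ci <- icc_consistency_k(paired_ratings(m1, m2))
    if (ci$ci_low <= truth && truth <= ci$ci_high) hits <- hits + 1L
  }
  coverage <- hits / n_sim
  expect_gte(coverage, 0.91)
  expect_lte(coverage, 0.99)
})

test_that("Bland-Altman summaries match hand computation", {
  x <- c(3, 4, 5, 6)
  ba0 <- bland_altman(paired_ratings(x, x))
  expect_equal(ba0$mean_difference, 0)
  expect_equal(ba0$sd_difference, 0)
  expect_equal(ba0$limits, c(0, 0))

  ba <- bland_altman(paired_ratings(c(1.25, 1.75), c(1, 2)))  # diffs +-0.25
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, sqrt(2 * 0.25^2 / 1), tolerance = 1e-12)

  bac <- bland_altman(paired_ratings(x + 0.4, x))             # constant diff
  expect_equal(bac$mean_difference, 0.4)
  expect_equal(bac$sd_difference, 0)
  expect_equal(bac$limits, c(0.4, 0.4))
})

test_that("sweep comparison joins on ML and reports identity perfectly", {
  a <- data.frame(ml_mm = seq(0, 6, 1), dd_mm = c(5.5, 5, 4.5, 4.5, 4, 3.5, 3.25))
  rep <- compare_sweeps(a, a)
  expect_equal(rep$icc, 1)
  expect_equal(rep$mean_difference, 0)
  b <- a
  b$ml_mm[3] <- 2.5
  expect_error(compare_sweeps(a, b), "ML keys do not match.*2.5")
  # MLs with no dislocation in either method are dropped from the pairing
  c1 <- a; c1$dd_mm[1] <- NA
  rep2 <- compare_sweeps(c1, a)
  expect_identical(rep2$n, 6L)
})
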