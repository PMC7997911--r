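test_that("permutation test separates shifted groups and respects the add-one bound", {
  set.seed(2)
  a <- rnorm(15, 0, 1)
  b <- rnorm(15, 3, 1)
  out <- permutation_test_means(a, b, n_perm = 2000, seed = 3)
  expect_equal(out$statistic, mean(a) - mean(b))
  expect_lte(out$p_value, 0.01)
  expect_gte(out$p_value, 1 / 2001)
  same <- permutation_test_means(rnorm(10), rnorm(10), n_perm = 500, seed = 4)
  expect_gt(same$p_value, 0.05)
  expect_error(permutation_test_means(1, 1:5), "at least 2")
})

test_that("fdr_bh matches the hand-computed step-up adjustment", {
  p <- c(0.005, 0.04, 0.02, 0.9)
  # sorted: .005*4/1=.02, .02*4/2=.04, .04*4/3=.0533, .9
  expect_equal(fdr_bh(p), c(0.02, 16 * 0.04 / 12, 0.04, 0.9), tolerance = 1e-9)
  expect_true(all(fdr_bh(p) >= p))
  expect_error(fdr_bh(c(0.5, 1.2)))
})

test_that("paired_series keeps complete pairs only", {
  ps <- paired_series(c(1, NA, 3), c(4, 5, NA),
                      labels = data.frame(subj = 1:3))
  expect_equal(nrow(ps), 1L)
  expect_equal(attr(ps, "n_dropped"), 2L)
  expect_equal(ps$subj, 1L)
})

test_that("bland_altman computes the standard quantities", {
  test <- c(10, 12, 11, 14, 13, 15, 12, 10)
  retest <- test + c(1, -1, 0.5, 0.2, -0.3, 1.1, 0.4, -0.6)
  ba <- bland_altman(paired_series(test, retest))
  d <- retest - test
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$sd_diff, sd(d))
  expect_equal(ba$loa_lower, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d))
  tq <- qt(0.975, 7)
  expect_equal(ba$ci_mean, mean(d) + c(-1, 1) * tq * sd(d) / sqrt(8))
  expect_error(bland_altman(paired_series(1:2, 2:3)), "at least 3")
})

test_that("icc_oneway is 1 for perfect agreement and labelled sensibly", {
  x <- rnorm(30, 0, 5)
  perfect <- icc_oneway(paired_series(x, x))
  expect_equal(perfect$icc, 1, tolerance = 1e-9)
  expect_equal(perfect$label, "excellent")
  set.seed(5)
  subj <- rnorm(200, 0, 1)
  noisy <- icc_oneway(paired_series(subj + rnorm(200, 0, 2),
                                    subj + rnorm(200, 0, 2)))
  expect_equal(noisy$label, "poor")
  expect_lt(noisy$ci[1], noisy$icc)
  expect_gt(noisy$ci[2], noisy$icc)
})

test_that("shepherds_pi removes gross outliers and doubles the p-value", {
  set.seed(6)
  x <- rnorm(30)
  y <- x + rnorm(30, 0, 0.2)
  clean <- shepherds_pi(x, y, seed = 7)
  expect_gt(clean$pi, 0.9)
  expect_lte(clean$n_removed, 3L)  # may trim a few edge points
  x2 <- c(x, 10); y2 <- c(y, -10)
  dirty <- shepherds_pi(x2, y2, seed = 7)
  expect_gte(dirty$n_removed, 1L)
  expect_true(31 %in% dirty$outliers)
  expect_lte(dirty$p_value, 1)
  expect_error(shepherds_pi(1:3, 1:3), "at least 5")
})

test_that("normality_check returns a Shapiro p-value and Q-Q data", {
  set.seed(8)
  out <- normality_check(rnorm(100))
  expect_gt(out$shapiro_p, 0.001)
  expect_length(out$qq$x, 100)
})
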