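# Group-comparison and test-retest repeatability statistics.

#' Two-sample permutation test for equality of means
#'
#' The statistic is the difference of group means (`mean(a) - mean(b)`); its
#' null distribution is obtained by randomly repartitioning the pooled values
#' into groups of the original sizes. The two-sided p-value uses the add-one
#' convention `(1 + #{|perm| >= |obs|}) / (n_perm + 1)`.
#'
#' @param a,b Numeric vectors (each at least two values).
#' @param n_perm Number of permutations (default 50000).
#' @param seed Optional seed for reproducibility.
#' @return List with `statistic`, `p_value`, `n_perm`.
#' @export
permutation_test_means <- function(a, b, n_perm = 50000, seed = NULL) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 values")
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  if (max(pool) == min(pool))
    return(list(statistic = 0, p_value = 1, n_perm = n_perm))
  na <- length(a); n <- length(pool); tot <- sum(pool)
  perm <- replicate(n_perm, {
    sa <- sum(pool[sample.int(n, na)])
    sa / na - (tot - sa) / (n - na)
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(statistic = obs, p_value = p, n_perm = n_perm)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values (same order as input).
#' @export
fdr_bh <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Paired test-retest series
#'
#' Pairs with a missing member are removed, as repeatability analyses use
#' complete pairs only.
#'
#' @param test,retest Numeric vectors of equal length.
#' @param labels Optional data.frame of per-pair keys (subject, frequency,
#'   level, ...).
#' @return Object of class `paired_series` (a data.frame), with attribute
#'   `n_dropped`.
#' @export
paired_series <- function(test, retest, labels = NULL) {
  stopifnot(length(test) == length(retest))
  d <- data.frame(test = test, retest = retest)
  if (!is.null(labels)) d <- cbind(d, labels)
  keep <- stats::complete.cases(d[, c("test", "retest")])
  out <- d[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("paired_series", "data.frame")
  out
}

#' Bland-Altman agreement analysis
#'
#' Differences are `retest - test`; the limits of agreement (LoA) are the
#' mean difference +/- 1.96 standard deviations of the differences. The
#' confidence interval of the mean uses `t * SD / sqrt(n)`; each LoA uses
#' the standard variance approximation `t * SD * sqrt(3 / n)`.
#'
#' @param pairs A [paired_series()] (columns `test`, `retest`).
#' @param ci_level Confidence level (default 0.95).
#' @return Object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `ci_mean`, `ci_loa_lower`, `ci_loa_upper`,
#'   `n`.
#' @export
bland_altman <- function(pairs, ci_level = 0.95) {
  d <- pairs$retest - pairs$test
  n <- length(d)
  if (n < 3) stop("Bland-Altman analysis needs at least 3 complete pairs")
  m <- mean(d); s <- stats::sd(d)
  tq <- stats::qt(1 - (1 - ci_level) / 2, n - 1)
  loa <- m + c(-1, 1) * 1.96 * s
  structure(list(mean_diff = m, sd_diff = s,
                 loa_lower = loa[1], loa_upper = loa[2],
                 ci_mean = m + c(-1, 1) * tq * s / sqrt(n),
                 ci_loa_lower = loa[1] + c(-1, 1) * tq * s * sqrt(3 / n),
                 ci_loa_upper = loa[2] + c(-1, 1) * tq * s * sqrt(3 / n),
                 n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, mean diff = %.3f (CI %.3f, %.3f), LoA = [%.3f, %.3f]\n",
              x$n, x$mean_diff, x$ci_mean[1], x$ci_mean[2],
              x$loa_lower, x$loa_upper))
  invisible(x)
}

#' One-way random-effects single-rater intraclass correlation, ICC(1,1)
#'
#' Computed from the one-way ANOVA mean squares with k = 2 sessions per
#' subject: `(MSB - MSW) / (MSB + (k-1) MSW)`. The confidence interval uses
#' the exact one-way F interval. The qualitative label follows the usual
#' guideline cut-offs (poor < 0.5 <= moderate < 0.75 <= good < 0.9 <=
#' excellent).
#'
#' @param pairs A [paired_series()].
#' @param ci_level Confidence level.
#' @return List with `icc`, `ci`, `label`, `n`.
#' @export
icc_oneway <- function(pairs, ci_level = 0.95) {
  x <- as.matrix(pairs[, c("test", "retest")])
  n <- nrow(x); k <- 2
  grand <- mean(x)
  msb <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msw <- sum((x - rowMeans(x))^2) / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  alpha <- 1 - ci_level
  f <- msb / msw
  fl <- f / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
  fu <- f * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
  ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  lab <- if (icc < 0.5) "poor" else if (icc < 0.75) "moderate"
         else if (icc < 0.9) "good" else "excellent"
  list(icc = icc, ci = ci, label = lab, n = n)
}

#' Shepherd's pi robust correlation
#'
#' Each point receives a bootstrapped Mahalanobis distance (the mean of its
#' squared Mahalanobis distances from the center and covariance of bootstrap
#' resamples of the data); points with distance > 6 are removed, Spearman
#' correlation is computed on the survivors, and the p-value is doubled to
#' pay for the outlier removal.
#'
#' @param x,y Paired numeric vectors (n >= 5).
#' @param seed Optional seed for the bootstrap.
#' @param n_boot Number of bootstrap resamples.
#' @return List with `pi`, `p_value`, `n_removed`, `outliers` (indices).
#' @export
shepherds_pi <- function(x, y, seed = NULL, n_boot = 200) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("Shepherd's pi needs at least 5 complete pairs")
  if (!is.null(seed)) set.seed(seed)
  xy <- cbind(x, y)
  d2 <- matrix(0, n, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    s <- xy[idx, , drop = FALSE]
    cv <- stats::cov(s)
    if (det(cv) < 1e-12) { d2[, b] <- 0; next }
    d2[, b] <- stats::mahalanobis(xy, colMeans(s), cv)
  }
  dist <- rowMeans(d2)
  keep <- dist <= 6
  if (!any(keep)) stop("all points removed as outliers; pi undefined")
  ct <- suppressWarnings(
    stats::cor.test(x[keep], y[keep], method = "spearman", exact = FALSE))
  list(pi = unname(ct$estimate), p_value = min(1, 2 * ct$p.value),
       n_removed = sum(!keep), outliers = which(!keep))
}

#' Normality check helper (advisory)
#'
#' @param x Numeric vector.
#' @return List with the Shapiro-Wilk p-value and the data for a Q-Q plot.
#' @export
normality_check <- function(x) {
  x <- x[is.finite(x)]
  sw <- stats::shapiro.test(x)
  qq <- stats::qqnorm(x, plot.it = FALSE)
  list(shapiro_p = sw$p.value, qq = qq)
}
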