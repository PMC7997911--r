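# Constrained two-segment piecewise fitting of magnitude-level functions.

#' Fit a continuous two-segment piecewise-linear function
#'
#' Fits `f(L) = s1*(L - bx) + by` for `L < bx` and `s2*(L - bx) + by` for
#' `L >= bx` by least squares, with the lower slope constrained to exceed the
#' upper slope (`s1 > s2`). The break-point is initialized by a grid search
#' over interior candidate levels and refined by continuous optimization; the
#' slope constraint is enforced by reparameterizing `s2 = s1 - exp(delta)`.
#' Each segment must contain at least `min_per_segment` points.
#'
#' @param levels Stimulus levels (dB SPL), strictly increasing.
#' @param magnitudes Response magnitudes (dB), same length.
#' @param min_per_segment Minimum number of points per segment (default 3).
#' @return A `level_fit` object (`model_kind = "two_slope"`) with fields
#'   `s1`, `s2`, `bx`, `by`, `adj_r2`, `r2`, `rss`, `n_points_lower`,
#'   `n_points_upper`; or `NULL` if no feasible break-point exists.
#' @export
fit_two_slope <- function(levels, magnitudes, min_per_segment = 3) {
  ok <- is.finite(levels) & is.finite(magnitudes)
  L <- levels[ok]; y <- magnitudes[ok]
  if (is.unsorted(L, strictly = TRUE)) stop("levels must be strictly increasing")
  n <- length(L)
  if (n < 2 * min_per_segment) return(NULL)

  pred <- function(par, L) {
    s1 <- par[1]; s2 <- s1 - exp(par[2]); bx <- par[3]; by <- par[4]
    ifelse(L < bx, s1 * (L - bx) + by, s2 * (L - bx) + by)
  }
  rss_fun <- function(par) {
    if (par[3] <= L[min_per_segment] - 1e-9 ||
        par[3] >= L[n - min_per_segment + 1] + 1e-9) return(1e12)
    sum((y - pred(par, L))^2)
  }
  # Grid search over interior break candidates; for a fixed bx the model is
  # linear in (s1, s2, by) and solved exactly, then checked for feasibility.
  candidates <- L[seq(min_per_segment, n - min_per_segment + 1L)]
  candidates <- unique(c(candidates,
                         (candidates[-1] + candidates[-length(candidates)]) / 2))
  best <- NULL
  for (bx in candidates) {
    X <- cbind(pmin(L - bx, 0), pmax(L - bx, 0), 1)
    cf <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    s1 <- cf[1]; s2 <- cf[2]
    if (!(s1 > s2 + 1e-6)) next
    rss <- sum((y - X %*% cf)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = c(s1, log(s1 - s2), bx, cf[3]), rss = rss)
  }
  if (is.null(best)) return(NULL)
  opt <- stats::optim(best$par, rss_fun, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  par <- unname(if (opt$value <= best$rss) opt$par else best$par)
  s1 <- par[1]; s2 <- s1 - exp(par[2]); bx <- par[3]; by <- par[4]
  rss <- sum((y - pred(par, L))^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  p <- 4
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)
  structure(list(model_kind = "two_slope", s1 = s1, s2 = s2, bx = bx, by = by,
                 s = NA_real_, a = NA_real_, adj_r2 = adj_r2, r2 = r2,
                 rss = rss, n = n,
                 n_points_lower = sum(L <= bx), n_points_upper = sum(L >= bx)),
            class = "level_fit")
}

#' Fit a single-slope (first-order polynomial) magnitude-level function
#'
#' @inheritParams fit_two_slope
#' @return A `level_fit` object (`model_kind = "linear"`) with slope `s`
#'   (the compression estimate) and intercept `a`; `NULL` with fewer than two
#'   points.
#' @export
fit_linear <- function(levels, magnitudes) {
  ok <- is.finite(levels) & is.finite(magnitudes)
  L <- levels[ok]; y <- magnitudes[ok]
  n <- length(L)
  if (n < 2) return(NULL)
  fit <- stats::lm(y ~ L)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  adj_r2 <- if (n > 2) 1 - (1 - r2) * (n - 1) / (n - 2) else r2
  structure(list(model_kind = "linear", s1 = NA_real_, s2 = NA_real_,
                 bx = NA_real_, by = NA_real_,
                 s = unname(stats::coef(fit)[2]), a = unname(stats::coef(fit)[1]),
                 adj_r2 = adj_r2, r2 = r2, rss = rss, n = n,
                 n_points_lower = NA_integer_, n_points_upper = NA_integer_),
            class = "level_fit")
}

#' Select between the two-slope and linear magnitude-level models
#'
#' The two-slope fit is returned unless it is infeasible (constraint or
#' segment-count rule) or the linear model has the higher adjusted R^2. Only
#' statistically significant points should be supplied.
#'
#' @inheritParams fit_two_slope
#' @return A `level_fit` object, or `NULL` if not even a line can be fitted.
#' @export
select_model <- function(levels, magnitudes, min_per_segment = 3) {
  lin <- fit_linear(levels, magnitudes)
  two <- fit_two_slope(levels, magnitudes, min_per_segment)
  if (is.null(two)) return(lin)
  if (is.null(lin)) return(two)
  if (lin$adj_r2 >= two$adj_r2 - 1e-9) lin else two
}

#' Compression slope from a level fit
#'
#' For a linear fit the single slope is the compression estimate. For a
#' two-slope fit the relevant segment depends on the shape of the function:
#' recorded EFR magnitude-level functions grow compressively and then
#' saturate, so their compression estimate is the lower-segment slope,
#' whereas simulated level functions grow near-linearly at very low levels
#' and bend into compression, so theirs is the upper-segment slope.
#'
#' @param fit A `level_fit`.
#' @param regime `"lower"` (pre-break segment) or `"upper"` (post-break).
#' @return Slope in dB/dB, or `NA` for a `NULL` fit.
#' @export
compression_slope <- function(fit, regime = c("lower", "upper")) {
  if (is.null(fit)) return(NA_real_)
  regime <- match.arg(regime)
  if (fit$model_kind == "linear") return(fit$s)
  if (regime == "lower") fit$s1 else fit$s2
}

#' Two-point repeatability slope estimator
#'
#' The slope between the EFR magnitudes at 55 and 35 dB SPL:
#' `(mag55 - mag35) / 20`. Either magnitude missing (non-significant) gives a
#' missing result.
#'
#' @param mag_35,mag_55 Magnitudes (dB) at 35 and 55 dB SPL.
#' @return Slope in dB/dB, or `NA` if either point is missing.
#' @export
two_point_slope <- function(mag_35, mag_55) {
  ifelse(is.na(mag_35) | is.na(mag_55), NA_real_, (mag_55 - mag_35) / 20)
}

#' Predict from a level fit
#' @param object A `level_fit`.
#' @param levels Levels at which to evaluate.
#' @param ... Unused.
#' @export
predict.level_fit <- function(object, levels, ...) {
  if (object$model_kind == "linear") return(object$s * levels + object$a)
  ifelse(levels < object$bx,
         object$s1 * (levels - object$bx) + object$by,
         object$s2 * (levels - object$bx) + object$by)
}

#' @export
print.level_fit <- function(x, ...) {
  if (x$model_kind == "two_slope") {
    cat(sprintf("<level_fit two_slope> s1 = %.3f, s2 = %.3f dB/dB, break at %.1f dB SPL (%.1f dB), adj R2 = %.3f, n = %d\n",
                x$s1, x$s2, x$bx, x$by, x$adj_r2, x$n))
  } else {
    cat(sprintf("<level_fit linear> s = %.3f dB/dB, intercept = %.1f dB, adj R2 = %.3f, n = %d\n",
                x$s, x$a, x$adj_r2, x$n))
  }
  invisible(x)
}

#' Fit a magnitude-level function from the EFR pipeline
#'
#' Applies [select_model()] to the statistically significant points of a
#' `magnitude_level_function` (non-significant points are treated as missing).
#'
#' @param mlf A `magnitude_level_function` data.frame.
#' @param ... Passed to [select_model()].
#' @return A `level_fit` or `NULL`.
#' @export
fit_magnitude_level_function <- function(mlf, ...) {
  sig <- mlf[mlf$significant, , drop = FALSE]
  if (nrow(sig) < 2) return(NULL)
  select_model(sig$level_db_spl, sig$magnitude_db, ...)
}
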