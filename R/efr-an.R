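# Simulated EFRs at the auditory-nerve level: CF x level heatmaps, summed
# magnitude-level functions, on-/off-CF decomposition, impairment scenarios.

#' On-CF band around a carrier frequency
#'
#' The on-CF band spans half an octave below to a third of an octave above
#' the carrier (edges inclusive).
#'
#' @param carrier_hz Carrier frequency in Hz.
#' @return Numeric vector `c(cf_low, cf_high)` in Hz.
#' @export
on_cf_band <- function(carrier_hz) {
  c(carrier_hz * 2^(-1 / 2), carrier_hz * 2^(1 / 3))
}

# Complex single-sided amplitude of x at integer frequency f0 over a window
# of exactly 1 s starting at sample i0+1 (2|X|/N convention).
bin_amplitude <- function(x, fs, f0, i0) {
  idx <- (i0 + 1L):(i0 + fs)
  t <- (seq_along(idx) - 1L) / fs
  z <- sum(x[idx] * exp(-2i * pi * f0 * t))
  2 * z / fs
}

#' Simulate EFR_AN magnitude-level functions and heatmaps
#'
#' For each stimulus level, the four-SAM complex is run through the AN
#' population model; per-CF PSTHs are summed in the time domain (all CFs,
#' on-CF band, off-CF complement) and the magnitude at each modulation
#' frequency is read from the spectrum of a 1-s steady-state window
#' (onset excluded). The simulated noise floor is the expected
#' modulation-bin amplitude of Poisson spike-count fluctuations at the
#' scope's total spike rate, `sqrt(pi * Lambda) / T`; a magnitude is flagged
#' significant when it exceeds three times that floor.
#'
#' @param params A [cochlear_parameters()].
#' @param impairment An [impairment_profile()] or `NULL` (normal hearing).
#' @param levels_db_spl Per-component stimulus levels (default 5-100 in 5 dB
#'   steps).
#' @param carriers_hz,modulations_hz Stimulus component tables.
#' @param duration_s Stimulus duration (default 1.2 s).
#' @param onset_skip_s Steady-state window start (default 0.15 s).
#' @return Object of class `efr_an_result`: `level_functions` (data.frame
#'   with carrier, level, scope, magnitude_db, noise_floor_db, significant),
#'   `heatmap` (array `n_cf x n_levels x n_carriers` of per-CF magnitudes),
#'   `heatmap_significant` (same shape, logical), `cf_grid`, `levels`,
#'   `carriers`.
#' @export
simulate_efr_an <- function(params, impairment = NULL,
                            levels_db_spl = seq(5, 100, 5),
                            carriers_hz = c(498, 1000, 2005, 4011),
                            modulations_hz = c(81, 87, 93, 98),
                            duration_s = 1.2, onset_skip_s = 0.15) {
  if (is.null(impairment)) impairment <- impairment_profile(params)
  fs <- params$fs_model_hz
  if (any(abs(modulations_hz - round(modulations_hz)) > 1e-9))
    stop("modulation frequencies must be integers to fall on 1-s bins")
  i0 <- round(onset_skip_s * fs)
  n_cf <- length(params$cf_grid)
  n_lev <- length(levels_db_spl)
  n_car <- length(carriers_hz)
  scopes <- c("all_cf", "on_cf", "off_cf")
  heat <- array(NA_real_, c(n_cf, n_lev, n_car))
  heat_sig <- array(NA, c(n_cf, n_lev, n_car))
  lf <- expand.grid(level_db_spl = levels_db_spl, carrier_hz = carriers_hz,
                    scope = scopes, stringsAsFactors = FALSE)
  lf$modulation_hz <- modulations_hz[match(lf$carrier_hz, carriers_hz)]
  lf$magnitude_db <- NA_real_; lf$noise_floor_db <- NA_real_
  on_rows <- lapply(carriers_hz, function(fc) {
    b <- on_cf_band(fc)
    which(params$cf_grid >= b[1] & params$cf_grid <= b[2])
  })
  for (il in seq_len(n_lev)) {
    comps <- Map(function(fc, fm) sam_component(fc, fm, 0.85, levels_db_spl[il]),
                 carriers_hz, modulations_hz)
    stim <- make_multi_sam(comps, duration_s, fs)
    pop <- population_response(stim, fs, params, impairment)
    t_win <- (seq_len(fs) - 1L) / fs
    all_psth <- colSums(pop$psth_by_cf)
    lam_cf <- rowMeans(pop$psth_by_cf[, (i0 + 1L):(i0 + fs), drop = FALSE])
    for (ic in seq_len(n_car)) {
      fm <- modulations_hz[ic]
      on_idx <- on_rows[[ic]]
      # per-CF heatmap magnitudes + significance vs per-CF Poisson floor
      win <- pop$psth_by_cf[, (i0 + 1L):(i0 + fs), drop = FALSE]
      zz <- win %*% exp(-2i * pi * fm * t_win)
      mag_cf <- 2 * Mod(zz) / fs
      floor_cf <- sqrt(pi * pmax(lam_cf, 1e-12))
      heat[, il, ic] <- 20 * log10(pmax(mag_cf, 1e-12))
      heat_sig[, il, ic] <- mag_cf > 3 * floor_cf
      on_psth <- colSums(pop$psth_by_cf[on_idx, , drop = FALSE])
      sums <- list(all_cf = all_psth, on_cf = on_psth,
                   off_cf = all_psth - on_psth)
      lam <- c(all_cf = sum(lam_cf), on_cf = sum(lam_cf[on_idx]))
      lam["off_cf"] <- lam["all_cf"] - lam["on_cf"]
      for (sc in scopes) {
        a <- Mod(bin_amplitude(sums[[sc]], fs, fm, i0))
        row <- lf$level_db_spl == levels_db_spl[il] &
          lf$carrier_hz == carriers_hz[ic] & lf$scope == sc
        lf$magnitude_db[row] <- 20 * log10(max(a, 1e-12))
        lf$noise_floor_db[row] <- 20 * log10(sqrt(pi * max(lam[[sc]], 1e-12)))
      }
    }
  }
  lf$significant <- lf$magnitude_db > lf$noise_floor_db + 20 * log10(3)
  structure(list(level_functions = lf, heatmap = heat,
                 heatmap_significant = heat_sig,
                 cf_grid = params$cf_grid, levels = levels_db_spl,
                 carriers = carriers_hz, modulations = modulations_hz),
            class = "efr_an_result")
}

#' Extract one simulated magnitude-level function
#'
#' @param result An `efr_an_result`.
#' @param carrier_hz Carrier frequency.
#' @param scope `"all_cf"`, `"on_cf"` or `"off_cf"`.
#' @return data.frame ordered by level.
#' @export
efr_an_level_function <- function(result, carrier_hz,
                                  scope = c("all_cf", "on_cf", "off_cf")) {
  scope <- match.arg(scope)
  d <- result$level_functions
  d <- d[d$carrier_hz == carrier_hz & d$scope == scope, , drop = FALSE]
  d[order(d$level_db_spl), , drop = FALSE]
}

#' Fit the compression slope of a simulated level function
#'
#' Applies the same model selection as the experimental pipeline to the
#' statistically significant points. Simulated functions grow near-linearly
#' at very low levels and bend into compression, so the compression estimate
#' is the upper-segment slope when the two-slope model is selected.
#'
#' @param lf data.frame from [efr_an_level_function()] (columns
#'   `level_db_spl`, `magnitude_db`, `significant`).
#' @param level_range Optional `c(lo, hi)` restriction to the experimentally
#'   covered level range before fitting.
#' @return List with `slope` (dB/dB) and `fit` (the `level_fit`).
#' @export
fit_efr_an_slope <- function(lf, level_range = NULL) {
  d <- lf[lf$significant, , drop = FALSE]
  if (!is.null(level_range))
    d <- d[d$level_db_spl >= level_range[1] & d$level_db_spl <= level_range[2], ,
           drop = FALSE]
  if (nrow(d) < 2) return(list(slope = NA_real_, fit = NULL))
  fit <- select_model(d$level_db_spl, d$magnitude_db)
  list(slope = compression_slope(fit, regime = "upper"), fit = fit)
}

#' Apply uniform cochlear synaptopathy to an impairment profile
#'
#' Scales synapse survival uniformly across CF and fiber type by the
#' configured age-group survival fraction (fiber-type-agnostic synapse
#' loss).
#'
#' @param impairment An [impairment_profile()].
#' @param age_group `"1-50"` or `"50-75"`, or `NULL` to pass `survival`
#'   directly.
#' @param survival Survival fraction in [0, 1] (overrides `age_group`).
#' @param survival_table Named fractions per age group; inputs from human
#'   temporal-bone synapse counts.
#' @return Modified `impairment_profile`.
#' @export
apply_synaptopathy <- function(impairment, age_group = NULL, survival = NULL,
                               survival_table = c("1-50" = 0.73, "50-75" = 0.50)) {
  if (is.null(survival)) {
    if (is.null(age_group)) stop("give either age_group or survival")
    survival <- survival_table[[age_group]]
  }
  if (survival < 0 || survival > 1) stop("survival must lie in [0, 1]")
  impairment$synapse_survival <- impairment$synapse_survival * survival
  impairment
}

#' Mean audiogram of the mildly hearing-impaired group emulation
#'
#' Normal thresholds below 4 kHz and a mild (20-45 dB HL) high-frequency
#' loss at and above 4 kHz.
#' @return data.frame with `freq_hz`, `threshold_db_hl`.
#' @export
hi_mean_audiogram <- function() {
  data.frame(freq_hz = c(125, 250, 500, 1000, 2000, 3000, 4000, 6000, 8000),
             threshold_db_hl = c(5, 5, 10, 10, 15, 25, 35, 37, 40))
}

#' Run the impairment scenario suite and tabulate fitted slopes
#'
#' Scenarios: normal hearing; the mean mild high-frequency hearing loss with
#' the default 2/3 OHC + 1/3 IHC attribution; the same audiogram attributed
#' to OHC dysfunction only or IHC dysfunction only; and normal hearing with
#' uniform cochlear synaptopathy.
#'
#' @param params A [cochlear_parameters()].
#' @param scenarios Character subset of
#'   `c("nh", "hi", "ohc_only", "ihc_only", "cs")`.
#' @param cs_age_group Age group for the synaptopathy scenario.
#' @param ... Passed to [simulate_efr_an()].
#' @return List with `slopes` (data.frame scenario x carrier x scope) and
#'   `results` (the `efr_an_result` per scenario).
#' @export
scenario_suite <- function(params,
                           scenarios = c("nh", "hi", "ohc_only", "ihc_only", "cs"),
                           cs_age_group = "50-75", ...) {
  aud <- hi_mean_audiogram()
  profiles <- list(
    nh = impairment_profile(params),
    hi = fit_audiogram(aud, params, ohc_fraction = 2 / 3),
    ohc_only = fit_audiogram(aud, params, ohc_fraction = 1),
    ihc_only = fit_audiogram(aud, params, ohc_fraction = 0),
    cs = apply_synaptopathy(impairment_profile(params), cs_age_group)
  )
  results <- list(); rows <- list()
  for (sc in scenarios) {
    res <- simulate_efr_an(params, profiles[[sc]], ...)
    results[[sc]] <- res
    for (fc in res$carriers) {
      for (scope in c("all_cf", "on_cf", "off_cf")) {
        sl <- fit_efr_an_slope(efr_an_level_function(res, fc, scope))
        rows[[length(rows) + 1L]] <-
          data.frame(scenario = sc, carrier_hz = fc, scope = scope,
                     slope_db_per_db = sl$slope,
                     model_kind = if (is.null(sl$fit)) NA_character_
                                  else sl$fit$model_kind)
      }
    }
  }
  list(slopes = do.call(rbind, rows), results = results)
}

#' Plot an EFR_AN heatmap
#' @param result An `efr_an_result`.
#' @param carrier_hz Which carrier to plot.
#' @param ... Passed to [graphics::image()].
#' @export
plot_efr_an_heatmap <- function(result, carrier_hz, ...) {
  ic <- match(carrier_hz, result$carriers)
  graphics::image(result$levels, log2(result$cf_grid), t(result$heatmap[, , ic]),
                  xlab = "Stimulus level (dB SPL)", ylab = "CF (log2 Hz)", ...)
  b <- on_cf_band(carrier_hz)
  graphics::abline(h = log2(b), lty = 2, col = "orange")
}
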