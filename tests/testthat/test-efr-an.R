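# One small shared simulation for the structural checks.
tiny_params <- cochlear_parameters(n_cf = 24)
tiny_res <- simulate_efr_an(tiny_params, levels_db_spl = c(30, 60, 90),
                            carriers_hz = c(1000, 4011),
                            modulations_hz = c(87, 98))

test_that("on_cf_band spans -1/2 to +1/3 octave", {
  b <- on_cf_band(4000)
  expect_equal(b, c(4000 * 2^(-0.5), 4000 * 2^(1 / 3)))
})

test_that("simulate_efr_an returns a consistent result object", {
  lf <- tiny_res$level_functions
  expect_equal(nrow(lf), 3 * 2 * 3)  # levels x carriers x scopes
  expect_equal(dim(tiny_res$heatmap), c(24L, 3L, 2L))
  expect_true(all(is.finite(lf$magnitude_db)))
  # significance flag is exactly the 3x-floor rule
  expect_equal(lf$significant,
               lf$magnitude_db > lf$noise_floor_db + 20 * log10(3))
  expect_error(simulate_efr_an(tiny_params, modulations_hz = c(87.5, 98),
                               carriers_hz = c(1000, 4011)),
               "integers")
})

test_that("scopes decompose: on-CF and off-CF amplitudes sum to all-CF", {
  # complex amplitudes add linearly over CF, so |A_all| <= |A_on| + |A_off|
  lf <- tiny_res$level_functions
  for (L in unique(lf$level_db_spl)) {
    d <- lf[lf$carrier_hz == 4011 & lf$level_db_spl == L, ]
    a <- 10^(d$magnitude_db[match(c("all_cf", "on_cf", "off_cf"), d$scope)] / 20)
    expect_lte(a[1], a[2] + a[3] + 1e-9)
  }
})

test_that("efr_an_level_function extracts one ordered scope", {
  d <- efr_an_level_function(tiny_res, 4011, "on_cf")
  expect_equal(d$level_db_spl, c(30, 60, 90))
  expect_true(all(d$scope == "on_cf"))
})

test_that("fit_efr_an_slope reports the upper-regime slope", {
  L <- seq(5, 100, 5)
  mag <- ifelse(L < 40, 1.0 * (L - 40), 0.25 * (L - 40))
  lf <- data.frame(level_db_spl = L, magnitude_db = mag, significant = TRUE)
  out <- fit_efr_an_slope(lf)
  expect_equal(out$slope, 0.25, tolerance = 0.02)
  out2 <- fit_efr_an_slope(lf, level_range = c(45, 100))
  expect_equal(out2$slope, 0.25, tolerance = 0.02)
  expect_true(is.na(fit_efr_an_slope(lf[1, ])$slope))
})

test_that("apply_synaptopathy scales survival uniformly", {
  prof <- impairment_profile(tiny_params)
  cs <- apply_synaptopathy(prof, "50-75")
  expect_equal(cs$synapse_survival, prof$synapse_survival * 0.5)
  cs2 <- apply_synaptopathy(prof, survival = 0.25)
  expect_equal(unique(as.numeric(cs2$synapse_survival)), 0.25)
  expect_error(apply_synaptopathy(prof), "age_group or survival")
  expect_error(apply_synaptopathy(prof, survival = 2), "\\[0, 1\\]")
})

test_that("hi_mean_audiogram is normal below 4 kHz with a mild HF loss", {
  a <- hi_mean_audiogram()
  expect_true(all(a$threshold_db_hl[a$freq_hz < 3000] <= 15))
  expect_true(all(a$threshold_db_hl[a$freq_hz >= 4000] >= 20))
})

test_that("scenario_suite tabulates slopes per scenario/carrier/scope", {
  suite <- scenario_suite(tiny_params, scenarios = "nh",
                          levels_db_spl = seq(20, 90, 10),
                          carriers_hz = c(1000, 4011),
                          modulations_hz = c(87, 98))
  s <- suite$slopes
  expect_equal(nrow(s), 2 * 3)
  expect_setequal(unique(s$scope), c("all_cf", "on_cf", "off_cf"))
  expect_s3_class(suite$results$nh, "efr_an_result")
})
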