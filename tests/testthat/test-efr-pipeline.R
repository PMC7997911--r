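test_that("epoched_recording promotes matrices and validates epoch length", {
  m <- matrix(0, 4, 1024)
  r <- epoched_recording(m, 1024)
  expect_equal(dim(r$epochs), c(4L, 1024L, 1L))
  expect_error(epoched_recording(matrix(0, 4, 512), 1024), "1 s of samples")
})

test_that("band-pass keeps in-band sines and removes out-of-band ones", {
  fs <- 1024
  t <- (seq_len(fs) - 1) / fs
  mk <- function(f) epoched_recording(matrix(rep(sin(2 * pi * f * t), 2),
                                             2, fs, byrow = TRUE), fs)
  inband <- bandpass_zero_phase(mk(100))$epochs[1, , 1]
  low <- bandpass_zero_phase(mk(10))$epochs[1, , 1]
  keep <- 100:900  # avoid filter edge transients
  expect_gt(sd(inband[keep]) * sqrt(2), 0.95)
  expect_lt(sd(low[keep]) * sqrt(2), 0.05)
  # zero phase: the filtered in-band sine stays aligned with the original
  expect_gt(cor(inband[keep], sin(2 * pi * 100 * t)[keep]), 0.999)
})

test_that("artifact rejection removes only over-threshold epochs", {
  r <- make_test_recording(n_epochs = 8, noise_sd = 1)
  r$epochs[3, 100, 1] <- 500
  kept <- reject_artifacts(r, 80)
  expect_equal(attr(kept, "n_rejected"), 1L)
  expect_equal(attr(kept, "rejected_index"), 3L)
  expect_equal(kept$trigger_index, setdiff(1:8, 3))
  expect_error(reject_artifacts(r, 1e-9), "all epochs rejected")
})

test_that("trial formation concatenates epochs and reports leftovers", {
  r <- make_test_recording(n_epochs = 35, fs = 256, fm = 60)
  tr <- form_trials(r, epochs_per_trial = 16)
  expect_equal(dim(tr$trials), c(2L, 16L * 256L))
  expect_equal(tr$n_discarded, 3L)
  expect_equal(dim(tr$epoch_variances), c(2L, 16L))
  expect_error(form_trials(make_test_recording(n_epochs = 8), 16), "at least 16")
})

test_that("weighted average equals the plain mean for equal variances and downweights noisy trials", {
  trials <- rbind(rep(1, 8), rep(3, 8))
  vars <- matrix(1, 2, 2)
  expect_equal(weighted_average(trials, vars), rep(2, 8))
  vars2 <- matrix(c(1, 100), 2, 2, byrow = FALSE)
  w <- weighted_average(trials, vars2)
  expect_true(all(w < 1.1))  # dominated by the clean trial
  expect_error(weighted_average(trials, matrix(0, 2, 2)), "degenerate")
})

test_that("amplitude spectrum reads exact sine amplitudes", {
  fs <- 512
  t <- (seq_len(4 * fs) - 1) / fs
  x <- 2.5 * sin(2 * pi * 98 * t)
  sp <- amplitude_spectrum(x, fs)
  expect_equal(sp$resolution_hz, 0.25)
  k <- 98 / sp$resolution_hz + 1
  expect_equal(sp$amplitude[k], 2.5, tolerance = 1e-9)
})

test_that("f_test calibration, significance, and exclusions behave", {
  fs <- 512
  set.seed(7)
  t <- (seq_len(16 * fs) - 1) / fs
  x <- rnorm(length(t), 0, 1) + 1.5 * sin(2 * pi * 98 * t)
  sp <- amplitude_spectrum(x, fs)
  ft <- f_test(sp, 98, half_width_hz = 3)
  expect_true(ft$significant)
  expect_equal(ft$n_noise_bins, 96L)
  ft2 <- f_test(sp, 98, half_width_hz = 3, exclude_hz = c(97, 99))
  expect_equal(ft2$n_noise_bins, 94L)
  expect_equal(ft2$n_excluded, 2L)
  expect_error(f_test(sp, 98.01), "exact spectral bin")
})

test_that("phase-to-latency returns increments over the series minimum", {
  fm <- 98
  lat_ms <- c(5, 4.5, 4, 3.5)  # decreasing latency with level
  ph <- -(lat_ms / 1000 * 360 * fm) - 90
  out <- phase_to_latency(ph, fm)
  expect_equal(out, lat_ms - min(lat_ms), tolerance = 1e-9)
  ph[2] <- NA
  out2 <- phase_to_latency(ph, fm)
  expect_true(is.na(out2[2]))
  expect_equal(out2[-2], (lat_ms - min(lat_ms))[-2], tolerance = 1e-9)
})

test_that("analyze_efr_run recovers a planted response end to end", {
  rec <- make_test_recording(n_epochs = 16, fs = 1024, fm = 98, amp_uv = 1,
                             noise_sd = 0.5, level_db_spl = 60)
  out <- analyze_efr_run(rec, test_config())
  row <- out[out$modulation_hz == 98, ]
  expect_true(row$significant)
  expect_equal(row$magnitude_db, 0, tolerance = 1)  # 1 uV = 0 dB re 1 uV
  expect_equal(attr(out, "n_trials"), 1L)
})

test_that("analyze_efr_session orders levels and computes latency increments", {
  recs <- lapply(c(70, 50), function(L)
    make_test_recording(n_epochs = 16, amp_uv = 10^((L - 80) / 20),
                        noise_sd = 0.05, level_db_spl = L, seed = L))
  sess <- analyze_efr_session(recs, test_config())
  mlf <- sess[["4011Hz"]]
  expect_equal(mlf$level_db_spl, c(50, 70))
  expect_true(all(mlf$significant))
  expect_equal(diff(mlf$magnitude_db), 20, tolerance = 1)
})
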