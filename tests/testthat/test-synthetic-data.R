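test_that("duration table covers 20-80 dB SPL with longer low-level runs", {
  tab <- efr_duration_table()
  expect_equal(range(tab$level_db_spl), c(20, 80))
  expect_gte(tab$duration_min[1], max(tab$duration_min[tab$level_db_spl >= 70]))
})

test_that("true_efr_magnitude implements the piecewise and single-slope laws", {
  tr <- eeg_truth()
  r <- tr$carriers[tr$carriers$carrier_hz == 2005, ]
  expect_equal(true_efr_magnitude(tr, 2005, r$bx), r$by)
  expect_equal(true_efr_magnitude(tr, 2005, r$bx - 10), r$by - 10 * r$s1)
  expect_equal(true_efr_magnitude(tr, 2005, r$bx + 10), r$by + 10 * r$s2)
  # infinite break point: single slope anchored at 55 dB SPL
  r4 <- tr$carriers[tr$carriers$carrier_hz == 4011, ]
  expect_equal(true_efr_magnitude(tr, 4011, 75) - true_efr_magnitude(tr, 4011, 55),
               20 * r4$s1)
  expect_error(true_efr_magnitude(tr, 1234, 50), "unknown carrier")
})

test_that("pink noise generator matches the requested band-limited PSD", {
  set.seed(11)
  fs <- 1024
  v <- mean(replicate(200, var(efrcomp:::pink_noise_epoch(fs, fs, 0.5))))
  f <- 1:(fs / 2)
  target <- sum(ifelse(f >= 1 & f <= 500, 0.5 * (f / 100)^(-1), 0)) * (fs / fs)
  expect_equal(v, target, tolerance = 0.05 * target)
})

test_that("gen_eeg_session is reproducible and carries the planted signal", {
  tr <- eeg_truth(artifact_rate = 0, noise_psd_uv2hz = 0.02)
  s1 <- gen_eeg_session(tr, levels_db_spl = 60, fs = 512, seed = 5,
                        epochs_per_level = 8)
  s2 <- gen_eeg_session(tr, levels_db_spl = 60, fs = 512, seed = 5,
                        epochs_per_level = 8)
  expect_identical(s1[[1]]$epochs, s2[[1]]$epochs)
  expect_equal(dim(s1[[1]]$epochs), c(8L, 512L, 2L))
  # signal (98 Hz component, channel 1) matches the truth law + session offset
  avg <- colMeans(s1[[1]]$epochs[, , 1])
  a <- 2 * Mod(fft(avg))[98 + 1] / 512
  want <- true_efr_magnitude(tr, 4011, 60)
  expect_equal(20 * log10(a), want, tolerance = 3)  # session offset + noise
  # channel 2 carries no signal
  avg2 <- colMeans(s1[[1]]$epochs[, , 2])
  expect_lt(2 * Mod(fft(avg2))[98 + 1] / 512, a / 2)
})

test_that("gen_eeg_session plants artifacts where it says it does", {
  tr <- eeg_truth(artifact_rate = 0.5)
  s <- gen_eeg_session(tr, levels_db_spl = 60, fs = 512, seed = 6,
                       epochs_per_level = 20)
  idx <- attr(s[[1]], "artifact_epochs")
  expect_gt(length(idx), 2)
  peaks <- apply(abs(s[[1]]$epochs), 1, max)
  expect_true(all(peaks[idx] > 80))
  expect_true(all(peaks[-idx] < 80))
})

test_that("duration table drives epoch counts when no override is given", {
  tr <- eeg_truth(artifact_rate = 0)
  s <- gen_eeg_session(tr, levels_db_spl = 80, fs = 256, seed = 7)
  expect_equal(dim(s[[1]]$epochs)[1], round(5.6 * 60))
})

test_that("dpoae truth laws evaluate exactly", {
  tr <- dpoae_truth()
  b <- tr$bands[tr$bands$band_hz == 2000, ]
  expect_equal(true_dp_magnitude(tr, 2000, 50), b$intercept_db + 50 * b$slope)
  expect_error(true_dp_magnitude(tr, 123, 50), "unknown band")
})

test_that("gen_dpoae_session is reproducible with calibrated noise", {
  tr <- dpoae_truth()
  s1 <- gen_dpoae_session(tr, levels_db_spl = 50, seed = 2, n_pairs = 2)
  s2 <- gen_dpoae_session(tr, levels_db_spl = 50, seed = 2, n_pairs = 2)
  expect_identical(s1[[1]]$pairs[[1]]$a, s2[[1]]$pairs[[1]]$a)
  expect_equal(s1[[1]]$level_db_spl, 50)
  expect_length(s1[[1]]$pairs, 2)
  # analyzer noise estimate of one pair sits near the configured floor
  an <- dpoae_analyzer(s1[[1]]$sweep)
  noi <- lsf_frames((s1[[1]]$pairs[[1]]$a - s1[[1]]$pairs[[1]]$b) / 2, an)
  got <- band_readout(noi)
  expect_equal(mean(got), tr$noise_floor_db_spl, tolerance = 2)
})

test_that("gen_test_retest yields plausible paired magnitudes with F-test dropouts", {
  tr <- eeg_truth()
  d <- gen_test_retest(tr, n_subjects = 12, seed = 3)
  expect_equal(nrow(d), 12 * 4 * 3)
  ok <- complete.cases(d[, c("test", "retest")])
  expect_gt(mean(ok), 0.5)
  # magnitudes scatter around the per-subject truth
  resid <- c(d$test[ok], d$retest[ok]) - rep(d$true_magnitude_db[ok], 2)
  expect_lt(abs(mean(resid)), 2)
  expect_lt(sd(resid), 6)
  # identical seeds reproduce
  expect_identical(d, gen_test_retest(tr, n_subjects = 12, seed = 3))
})
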