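small_params <- cochlear_parameters(n_cf = 40)

test_that("cochlear_parameters builds a consistent parameter set", {
  p <- small_params
  expect_length(p$cf_grid, 40)
  expect_equal(range(p$cf_grid), c(125, 20000))
  expect_equal(sum(p$fiber_count), 32000)
  expect_true(all(diff(p$gain_db) >= 0))      # gain grows basally
  expect_true(all(diff(p$comp_exp) <= 0))     # compression strengthens basally
  expect_error(cochlear_parameters(sr_fractions = c(HSR = 0.5, MSR = 0.5, LSR = 0.5)))
})

test_that("impairment_profile validates and broadcasts", {
  prof <- impairment_profile(small_params, ohc_loss = 0.5)
  expect_equal(prof$ohc_loss, rep(0.5, 40))
  expect_equal(dim(prof$synapse_survival), c(40L, 3L))
  expect_error(impairment_profile(small_params, ohc_loss = 1.5), "\\[0, 1\\]")
})

test_that("middle ear is band-pass with a mid-frequency maximum", {
  r <- middle_ear_response(c(125, 2000, 20000))
  expect_gt(r[2], r[1])
  expect_gt(r[2], r[3])
  # waveform filtering preserves a mid-frequency tone better than edges
  fs <- 16000
  t <- (seq_len(fs) - 1) / fs
  y <- middle_ear(sin(2 * pi * 2000 * t), fs)
  expect_equal(sd(y) * sqrt(2), middle_ear_response(2000), tolerance = 0.01)
})

test_that("BM I/O curve is compressive at 4 kHz and linearizes with OHC loss", {
  p <- small_params
  L <- seq(5, 100, 5)
  io_nh <- bm_io_curve(p, 4000, L)
  io_ohc <- bm_io_curve(p, 4000, L, ohc_loss = 1)
  mid <- L >= 40 & L <= 80
  slope_nh <- coef(lm(io_nh[mid] ~ L[mid]))[2]
  expect_lt(slope_nh, 0.5)          # compressive mid-level growth
  expect_true(all(io_ohc <= io_nh + 1e-9))
  # without amplification growth is linear below the (elevated) knee
  lowslope_ohc <- coef(lm(io_ohc[L <= 40] ~ L[L <= 40]))[2]
  expect_equal(unname(lowslope_ohc), 1, tolerance = 0.05)
  # impaired curve converges onto the intact one at high levels
  expect_lt(io_nh[length(L)] - io_ohc[length(L)], 3)
})

test_that("bm_stage applies full gain at low level and less at high level", {
  p <- small_params
  cf <- p$cf_grid[which.min(abs(log(p$cf_grid / 4000)))]
  i <- which(p$cf_grid == cf)
  fs <- p$fs_model_hz
  t <- (seq_len(fs) - 1) / fs
  mk <- function(L) sqrt(2) * 20e-6 * 10^(L / 20) * sin(2 * pi * round(cf) * t)
  lo <- bm_stage(mk(5), fs, cf, p)
  hi <- bm_stage(mk(90), fs, cf, p)
  expect_equal(median(lo$gain), 10^(p$gain_db[i] / 20), tolerance = 0.05)
  expect_lt(median(hi$gain), 0.2 * 10^(p$gain_db[i] / 20))
  expect_error(bm_stage(mk(50), fs, 4321, p), "not on the model CF grid")
})

test_that("IHC stage is linear for small inputs, saturating, and shifted by IHC loss", {
  x <- seq(0, 5, length.out = 100)
  d <- ihc_stage(x, 16000, lowpass = FALSE)
  expect_equal(d[x < 0.05], x[x < 0.05], tolerance = 1e-3)
  expect_lt(max(d), 1 + 1e-9)   # saturation at IHC_SAT_PA = 1
  d_loss <- ihc_stage(x, 16000, ihc_loss = 0.5, lowpass = FALSE)
  expect_true(all(d_loss <= d + 1e-12))
  # 30 dB sensitivity loss in the linear regime
  expect_equal(d_loss[3] / d[3], 10^(-0.5 * 60 / 20), tolerance = 1e-2)
})

test_that("synapse rate-level curve is monotone with the expected spont rate", {
  drives <- 20e-6 * 10^(seq(0, 100, 10) / 20)
  r <- vapply(drives, function(d)
    synapse_rate(rep(d, 100), "HSR", 16000, adapt_strength = 0)[50],
    numeric(1))
  expect_true(all(diff(r) > 0))
  expect_equal(synapse_rate(rep(0, 10), "HSR", 16000, adapt_strength = 0)[5],
               60, tolerance = 1e-6)
  # LSR saturates higher: the half-way drive is larger
  r_lsr <- vapply(drives, function(d)
    synapse_rate(rep(d, 100), "LSR", 16000, adapt_strength = 0)[50],
    numeric(1))
  expect_lt(r_lsr[6] / max(r_lsr), r[6] / max(r))
})

test_that("adaptation produces onset overshoot and decays to steady state", {
  fs <- 16000
  d <- c(rep(0, 100), rep(0.01, 3 * fs %/% 2))
  r <- synapse_rate(d, "HSR", fs)
  onset <- max(r[101:300])
  steady <- mean(r[(length(r) - 1000):length(r)])
  expect_gt(onset, steady * 1.1)
})

test_that("fit_audiogram splits threshold elevation between OHC and IHC", {
  p <- small_params
  flat0 <- data.frame(freq_hz = c(125, 1000, 8000), threshold_db_hl = c(0, 0, 0))
  prof0 <- fit_audiogram(flat0, p)
  expect_equal(max(prof0$ohc_loss), 0)
  expect_equal(max(prof0$ihc_loss), 0)
  flat30 <- data.frame(freq_hz = c(125, 1000, 8000), threshold_db_hl = rep(30, 3))
  prof <- fit_audiogram(flat30, p)
  i <- which.min(abs(p$cf_grid - 4000))
  expect_equal(prof$ohc_loss[i] * p$gain_db[i], 20, tolerance = 0.5)
  expect_equal(prof$ihc_loss[i] * 60, 10, tolerance = 0.5)
  # OHC-only attribution caps at the available gain and reassigns the rest
  apical <- data.frame(freq_hz = c(125, 8000), threshold_db_hl = c(40, 40))
  prof2 <- fit_audiogram(apical, p, ohc_fraction = 1)
  expect_gt(max(attr(prof2, "reassigned_db")), 0)
})

test_that("population_response returns per-CF PSTHs with sane values", {
  p <- cochlear_parameters(n_cf = 12)
  stim <- make_sam_tone(sam_component(1000, 87, 0.85, 60), 1.2, p$fs_model_hz)
  pop <- population_response(stim, p$fs_model_hz, p)
  expect_equal(dim(pop$psth_by_cf), c(12L, 1.2 * p$fs_model_hz))
  expect_true(all(pop$psth_by_cf >= 0))
  expect_true(all(is.finite(pop$mean_rate_by_cf)))
  # the on-CF place responds above spontaneous activity
  i_on <- which.min(abs(log(p$cf_grid / 1000)))
  silence <- population_response(numeric(1.2 * p$fs_model_hz),
                                 p$fs_model_hz, p)
  expect_gt(pop$mean_rate_by_cf[i_on], silence$mean_rate_by_cf[i_on] * 1.2)
  expect_error(population_response(numeric(100), p$fs_model_hz, p),
               "at least 1.2 s")
})

test_that("Poisson sampling mode is seeded and mean-preserving", {
  p <- cochlear_parameters(n_cf = 6)
  stim <- make_sam_tone(sam_component(1000, 87, 0.85, 60), 1.2, p$fs_model_hz)
  s1 <- population_response(stim, p$fs_model_hz, p, sample_spikes = TRUE, seed = 9)
  s2 <- population_response(stim, p$fs_model_hz, p, sample_spikes = TRUE, seed = 9)
  expect_identical(s1$psth_by_cf, s2$psth_by_cf)
  ex <- population_response(stim, p$fs_model_hz, p)
  expect_equal(mean(s1$psth_by_cf), mean(ex$psth_by_cf), tolerance = 0.02)
})
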