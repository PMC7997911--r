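# A short, low-rate sweep keeps these tests fast; the analyzer rescales its
# window/step to the sampling rate.
short_sweep <- sweep_pair(f2_start_hz = 1000, f2_end_hz = 4000,
                          level_db_spl = 55, fs_hz = 16000)
suppressMessages(short_an <- dpoae_analyzer(short_sweep))
P_REF <- 20e-6

planted_recording <- function(sweep, dp_db_spl) {
  prim <- make_dpoae_sweep_pair(sweep)
  n <- length(prim$f1)
  t <- (seq_len(n) - 1) / sweep$fs_hz
  a <- sqrt(2) * P_REF * 10^(dp_db_spl / 20)
  prim$f1 + prim$f2 + a * sin(dp_phase(sweep, t))
}

test_that("dpoae_analyzer builds a consistent frame grid", {
  expect_s3_class(short_an, "dpoae_analyzer")
  expect_equal(short_an$window, 8000)  # 24000 * 16/48
  expect_gt(length(short_an$frames), 50)
  expect_true(all(diff(short_an$f2_at_frame) > 0))
  expect_message(dpoae_analyzer(short_sweep), "rescaled")
})

test_that("lsf_frames recovers a planted distortion chirp under the primaries", {
  rec <- planted_recording(short_sweep, -5)
  fr <- lsf_frames(rec, short_an)
  mid <- fr$f2_at_frame_hz > 1400 & fr$f2_at_frame_hz < 3200
  expect_equal(mean(fr$dp_magnitude_db[mid]), -5, tolerance = 0.1)
  expect_lt(sd(fr$dp_magnitude_db[mid]), 0.2)
})

test_that("phase-inversion noise estimate cancels deterministic content", {
  rec <- planted_recording(short_sweep, 0)
  set.seed(3)
  nz <- function() rnorm(length(rec), 0, 1e-4)
  out <- noise_from_pair(rec + nz(), rec + nz(), short_an)
  mid <- out$signal$f2_at_frame_hz > 1400 & out$signal$f2_at_frame_hz < 3200
  expect_equal(mean(out$signal$dp_magnitude_db[mid]), 0, tolerance = 0.2)
  # deterministic part cancelled: noise series far below the signal
  expect_lt(mean(out$noise$dp_magnitude_db_raw[mid]),
            mean(out$signal$dp_magnitude_db[mid]) - 20)
  expect_true(all(out$noise$dp_magnitude_db >= -30))
})

test_that("band_readout power-averages frames within 1/24 octave", {
  fr <- data.frame(f2_at_frame_hz = c(1990, 2000, 2010, 3000),
                   dp_amplitude_pa = c(1, 1, 1, 100) * sqrt(2) * P_REF)
  out <- band_readout(fr, bands_hz = c(2000, 4000))
  expect_equal(unname(out["2000Hz"]), 0, tolerance = 1e-9)
  expect_true(is.na(out["4000Hz"]))
})

test_that("stopping_rule stops on SNR or pair budget", {
  expect_equal(stopping_rule(c(12, 15, 11, 20), 2), "stop")
  expect_equal(stopping_rule(c(12, 8, 11, 20), 2), "continue")
  expect_equal(stopping_rule(c(NA, 8, 11, 20), 2), "continue")
  expect_equal(stopping_rule(c(0, 0, 0, 0), 8), "stop")
})

test_that("analyze_dpoae_level flags significance and stops early on clean pairs", {
  rec <- planted_recording(short_sweep, 0)
  set.seed(4)
  pairs <- lapply(1:3, function(i)
    list(a = rec + rnorm(length(rec), 0, 1e-5),
         b = rec + rnorm(length(rec), 0, 1e-5)))
  pts <- analyze_dpoae_level(pairs, short_an, level_db_spl = 55,
                             bands_hz = c(1500, 2000, 2500, 3000))
  expect_equal(attr(pts, "pairs_used"), 1L)
  expect_true(all(pts$significant))
  expect_equal(pts$magnitude_db, rep(0, 4), tolerance = 0.3)
})

test_that("dpoae_slope fits the significant points only", {
  pts <- data.frame(level_db_spl = seq(30, 65, 5),
                    magnitude_db = 0.6 * seq(30, 65, 5) - 30,
                    significant = TRUE)
  pts$significant[1] <- FALSE
  pts$magnitude_db[1] <- 10  # outlier that must be excluded
  f <- dpoae_slope(pts)
  expect_equal(f$s, 0.6, tolerance = 1e-9)
  pts$significant <- FALSE
  expect_null(dpoae_slope(pts))
})
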