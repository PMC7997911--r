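# Seeded generators for EEG sessions, DPOAE sweep recordings and test-retest
# datasets with known ground truth.

#' Stimulus-duration table for EFR runs
#'
#' Recording duration (minutes) per stimulus level, longer at low levels
#' where the response is weak: 12 min at 20 dB SPL tapering to 5.6 min at
#' 70-80 dB SPL.
#'
#' @return data.frame with `level_db_spl` and `duration_min`.
#' @export
efr_duration_table <- function() {
  data.frame(level_db_spl = seq(20, 80, 5),
             duration_min = c(12, 12, 11.2, 10.13, 8.53, 8.53, 7.73, 7.2,
                              7.2, 6.67, 5.6, 5.6, 5.6))
}

#' Ground truth for synthetic EEG sessions
#'
#' Per-carrier two-slope magnitude-level laws (dB re 1 uV), a linear
#' latency-versus-level law, a 1/f^gamma background-noise model, artifact
#' plumbing and between-session variability. An infinite break-point `bx`
#' denotes a single-slope law. Defaults emulate normal-hearing group
#' medians: compressive growth of about 0.2-0.3 dB/dB with saturation above
#' 55-60 dB SPL at the three lower carriers and monotonic single-slope
#' growth at 4 kHz.
#'
#' @param carriers data.frame with columns `carrier_hz`, `modulation_hz`,
#'   `s1`, `s2`, `bx`, `by` (level law) or `NULL` for the defaults.
#' @param latency_ms_at_20db,latency_slope_ms_per_db Latency law:
#'   `latency(L) = latency_ms_at_20db - slope * (L - 20)`.
#' @param noise_psd_uv2hz One-sided EEG noise power spectral density at
#'   100 Hz (uV^2/Hz).
#' @param noise_gamma 1/f exponent of the noise spectrum.
#' @param artifact_rate Per-epoch artifact probability.
#' @param artifact_amp_uv Artifact burst amplitude.
#' @param session_jitter_db SD of the per-session magnitude offset.
#' @return Object of class `eeg_truth`.
#' @export
eeg_truth <- function(carriers = NULL,
                      latency_ms_at_20db = 9, latency_slope_ms_per_db = 0.059,
                      noise_psd_uv2hz = 0.5, noise_gamma = 1,
                      artifact_rate = 0.05, artifact_amp_uv = 200,
                      session_jitter_db = 1.5) {
  if (is.null(carriers)) {
    carriers <- data.frame(
      carrier_hz = c(498, 1000, 2005, 4011),
      modulation_hz = c(81, 87, 93, 98),
      s1 = c(0.24, 0.31, 0.27, 0.21),
      s2 = c(0.02, 0.02, 0.02, NA),
      bx = c(55, 60, 60, Inf),
      by = c(-12, -10, -11, -7.2))
  }
  stopifnot(artifact_rate >= 0, artifact_rate <= 1, noise_psd_uv2hz > 0)
  structure(list(carriers = carriers,
                 latency_ms_at_20db = latency_ms_at_20db,
                 latency_slope_ms_per_db = latency_slope_ms_per_db,
                 noise_psd_uv2hz = noise_psd_uv2hz, noise_gamma = noise_gamma,
                 artifact_rate = artifact_rate,
                 artifact_amp_uv = artifact_amp_uv,
                 session_jitter_db = session_jitter_db),
            class = "eeg_truth")
}

#' True EFR magnitude (dB re 1 uV) under a truth law
#' @param truth An [eeg_truth()].
#' @param carrier_hz Carrier.
#' @param level_db_spl Stimulus level(s).
#' @return Magnitudes in dB re 1 uV.
#' @export
true_efr_magnitude <- function(truth, carrier_hz, level_db_spl) {
  r <- truth$carriers[truth$carriers$carrier_hz == carrier_hz, ]
  if (nrow(r) != 1) stop("unknown carrier")
  if (is.finite(r$bx)) {
    ifelse(level_db_spl < r$bx,
           r$s1 * (level_db_spl - r$bx) + r$by,
           r$s2 * (level_db_spl - r$bx) + r$by)
  } else {
    # single-slope law: by holds the magnitude at 55 dB SPL
    r$by + r$s1 * (level_db_spl - 55)
  }
}

# 1/f^gamma Gaussian noise, band-limited to [lo, hi] Hz, with one-sided PSD
# `psd_ref` uV^2/Hz at `f_ref`. Built in the frequency domain with exact
# Hermitian symmetry.
pink_noise_epoch <- function(n, fs, psd_ref, gamma = 1, f_ref = 100,
                             lo = 1, hi = 500) {
  nh <- floor(n / 2)
  f <- (1:nh) * fs / n
  psd <- ifelse(f >= lo & f <= hi, psd_ref * (f / f_ref)^(-gamma), 0)
  df <- fs / n
  # component amplitude a_k, b_k ~ N(0, psd*df); X[k+1] = (n/2)(a - i b)
  a <- stats::rnorm(nh, 0, sqrt(psd * df))
  b <- stats::rnorm(nh, 0, sqrt(psd * df))
  X <- complex(length.out = n)
  X[2:(nh + 1)] <- (n / 2) * complex(real = a, imaginary = -b)
  if (n %% 2 == 0) X[nh + 1] <- complex(real = n * a[nh] / 2)  # Nyquist real
  X[n:(n - nh + 2)] <- Conj(X[2:nh])
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Generate a synthetic EEG session
#'
#' Each 1-s epoch contains four sinusoids at the modulation frequencies
#' whose amplitudes follow the truth's magnitude-level law at the run level
#' (with latency-law phase), embedded in 1/f Gaussian noise, with Bernoulli
#' artifact epochs (half-sine bursts on a random channel). Per-level epoch
#' counts follow the duration table unless overridden.
#'
#' @param truth An [eeg_truth()].
#' @param levels_db_spl Stimulus levels of the session runs.
#' @param fs Stored EEG sampling rate (default 4096 Hz).
#' @param seed Seed; identical seeds give bit-identical sessions.
#' @param epochs_per_level Optional count (scalar or per level) overriding
#'   the duration table (useful for reduced-scale studies).
#' @param session_offset_db Session-level magnitude offset; `NULL` draws one
#'   from the truth's `session_jitter_db`.
#' @param n_channels Number of EEG channels (signal appears on channel 1,
#'   the derived montage channel).
#' @return List of [epoched_recording()] objects (one per level), with the
#'   planted per-epoch artifact indices as attribute `artifact_epochs`.
#' @export
gen_eeg_session <- function(truth, levels_db_spl = seq(20, 80, 5), fs = 4096,
                            seed = 1, epochs_per_level = NULL,
                            session_offset_db = NULL, n_channels = 2) {
  set.seed(seed)
  tab <- efr_duration_table()
  if (is.null(epochs_per_level)) {
    dur <- stats::approx(tab$level_db_spl, tab$duration_min,
                         xout = levels_db_spl, rule = 2)$y
    epochs_per_level <- round(dur * 60)
  } else {
    epochs_per_level <- rep_len(epochs_per_level, length(levels_db_spl))
  }
  if (is.null(session_offset_db))
    session_offset_db <- stats::rnorm(1, 0, truth$session_jitter_db)
  t <- (seq_len(fs) - 1L) / fs
  out <- vector("list", length(levels_db_spl))
  for (il in seq_along(levels_db_spl)) {
    L <- levels_db_spl[il]
    n_ep <- epochs_per_level[il]
    lat_s <- (truth$latency_ms_at_20db -
                truth$latency_slope_ms_per_db * (L - 20)) / 1000
    sig <- numeric(fs)
    for (ic in seq_len(nrow(truth$carriers))) {
      r <- truth$carriers[ic, ]
      A <- 10^((true_efr_magnitude(truth, r$carrier_hz, L) +
                  session_offset_db) / 20)
      sig <- sig + A * sin(2 * pi * r$modulation_hz * (t - lat_s))
    }
    ep <- array(0, c(n_ep, fs, n_channels))
    is_artifact <- stats::runif(n_ep) < truth$artifact_rate
    for (ie in seq_len(n_ep)) {
      for (ch in seq_len(n_channels)) {
        ep[ie, , ch] <- pink_noise_epoch(fs, fs, truth$noise_psd_uv2hz,
                                         truth$noise_gamma) +
          if (ch == 1) sig else 0
      }
      if (is_artifact[ie]) {
        ch <- sample.int(n_channels, 1)
        ep[ie, , ch] <- ep[ie, , ch] + truth$artifact_amp_uv * sin(pi * t)
      }
    }
    rec <- epoched_recording(ep, fs, level_db_spl = L)
    attr(rec, "artifact_epochs") <- which(is_artifact)
    out[[il]] <- rec
  }
  out
}

#' Ground truth for synthetic DPOAE sessions
#'
#' Per-band linear distortion-product level laws
#' `dp_db(L) = intercept + slope * L` and a stationary noise floor, given as
#' the level the analyzer reports for one averaged sweep pair. Default
#' slopes emulate normal-hearing group medians.
#'
#' @param bands data.frame with `band_hz`, `slope`, `intercept_db` or `NULL`
#'   for defaults.
#' @param noise_floor_db_spl Reported per-pair noise level.
#' @return Object of class `dpoae_truth`.
#' @export
dpoae_truth <- function(bands = NULL, noise_floor_db_spl = -30) {
  if (is.null(bands)) {
    bands <- data.frame(band_hz = c(500, 1000, 2000, 4000),
                        slope = c(0.5, 0.74, 0.44, 0.72),
                        intercept_db = c(-25, -38, -19, -36))
  }
  structure(list(bands = bands, noise_floor_db_spl = noise_floor_db_spl),
            class = "dpoae_truth")
}

#' True DPOAE magnitude under a truth law
#' @param truth A [dpoae_truth()].
#' @param band_hz Band.
#' @param level_db_spl Primary level(s).
#' @return Magnitudes in dB SPL.
#' @export
true_dp_magnitude <- function(truth, band_hz, level_db_spl) {
  r <- truth$bands[truth$bands$band_hz == band_hz, ]
  if (nrow(r) != 1) stop("unknown band")
  r$intercept_db + r$slope * level_db_spl
}

#' Generate synthetic DPOAE sweep-pair recordings
#'
#' Each recording contains the two swept primaries plus a 2f1-f2 distortion
#' chirp whose amplitude follows the truth law (interpolated in log-f2
#' between the band anchors) and Gaussian noise calibrated so that the
#' analyzer's per-pair noise estimate equals the truth's floor.
#'
#' @param truth A [dpoae_truth()].
#' @param levels_db_spl Primary levels (default 30-65 dB SPL in 5 dB steps).
#' @param seed Seed.
#' @param n_pairs Sweep pairs generated per level (>= 8 so the stopping rule
#'   can always run its course).
#' @param sweep_template A [sweep_pair()] used for geometry (level is
#'   overridden per run).
#' @param analyzer_window Analyzer window length used for the noise
#'   calibration (must match the analysis window).
#' @return List with one element per level: `level_db_spl`, `pairs` (list of
#'   `list(a, b)` recordings), `sweep`.
#' @export
gen_dpoae_session <- function(truth, levels_db_spl = seq(30, 65, 5), seed = 1,
                              n_pairs = 8, sweep_template = sweep_pair(),
                              analyzer_window = 24000) {
  set.seed(seed)
  fs <- sweep_template$fs_hz
  n <- round(sweep_template$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  fq <- sweep_frequencies(sweep_template, t)
  ph <- dp_phase(sweep_template, t)
  lf2 <- log2(fq$f2)
  # white-noise SD so that the Hann-LSF noise estimate of one averaged pair
  # has expected power equal to the truth floor: E[A^2] = 6 sigma_eff^2 / N,
  # sigma_eff = sigma / sqrt(2)
  a_floor <- sqrt(2) * P_REF * 10^(truth$noise_floor_db_spl / 20)
  sigma <- a_floor * sqrt(analyzer_window / 3)
  out <- vector("list", length(levels_db_spl))
  for (il in seq_along(levels_db_spl)) {
    L <- levels_db_spl[il]
    sw <- sweep_template
    sw$level_db_spl <- L
    prim <- make_dpoae_sweep_pair(sw)
    mag_db <- stats::approx(log2(truth$bands$band_hz),
                            truth$bands$intercept_db + truth$bands$slope * L,
                            xout = lf2, rule = 2)$y
    dp_amp <- sqrt(2) * P_REF * 10^(mag_db / 20)
    det_part <- prim$f1 + prim$f2 + dp_amp * sin(ph)
    pairs <- lapply(seq_len(n_pairs), function(i) {
      list(a = det_part + stats::rnorm(n, 0, sigma),
           b = det_part + stats::rnorm(n, 0, sigma))
    })
    out[[il]] <- list(level_db_spl = L, pairs = pairs, sweep = sw)
  }
  out
}

#' Generate a synthetic test-retest EFR dataset
#'
#' Emulates the repeatability design (levels 35/55/70 dB SPL recorded twice
#' per subject) through an analytic spectral model: each measurement is a
#' planted complex modulation-bin amplitude (subject- and session-level
#' offsets applied in dB) perturbed by a complex Gaussian spectral noise
#' bin, and the spectral F-test (signal power over the mean of 96
#' chi-squared noise bins) decides significance exactly as in the recording
#' pipeline. Missing points therefore arise naturally from failed F-tests.
#'
#' @param truth An [eeg_truth()].
#' @param n_subjects Number of synthetic subjects.
#' @param seed Seed.
#' @param levels_db_spl Levels measured twice.
#' @param between_subject_sd_db SD of subject-level magnitude offsets.
#' @param noise_floor_db Mean spectral noise-bin level (dB re 1 uV).
#' @return data.frame with subject, carrier, level, session magnitudes
#'   (`test`, `retest`, `NA` when not significant) and true magnitudes.
#' @export
gen_test_retest <- function(truth, n_subjects = 20, seed = 1,
                            levels_db_spl = c(35, 55, 70),
                            between_subject_sd_db = 3,
                            noise_floor_db = -30) {
  set.seed(seed)
  noise_amp <- 10^(noise_floor_db / 20)
  # mean amplitude of a Rayleigh bin = sigma*sqrt(pi/2)
  sg <- noise_amp / sqrt(pi / 2)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    subj_off <- stats::rnorm(1, 0, between_subject_sd_db)
    for (ic in seq_len(nrow(truth$carriers))) {
      r <- truth$carriers[ic, ]
      for (L in levels_db_spl) {
        A_true <- 10^((true_efr_magnitude(truth, r$carrier_hz, L) + subj_off) / 20)
        meas <- vapply(1:2, function(sess) {
          sess_off <- stats::rnorm(1, 0, truth$session_jitter_db)
          A <- A_true * 10^(sess_off / 20)
          z <- complex(real = A + stats::rnorm(1, 0, sg / sqrt(2)),
                       imaginary = stats::rnorm(1, 0, sg / sqrt(2)))
          noise_bins <- (stats::rnorm(96, 0, sg / sqrt(2))^2 +
                           stats::rnorm(96, 0, sg / sqrt(2))^2)
          f_ratio <- Mod(z)^2 / mean(noise_bins)
          p <- stats::pf(f_ratio, 2, 96, lower.tail = FALSE)
          if (p <= 0.01) 20 * log10(Mod(z)) else NA_real_
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, carrier_hz = r$carrier_hz, level_db_spl = L,
          test = meas[1], retest = meas[2],
          true_magnitude_db = 20 * log10(A_true))
      }
    }
  }
  do.call(rbind, rows)
}
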