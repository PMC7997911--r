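# Swept-primary DPOAE analysis: windowed least-squares extraction of the
# 2f1-f2 distortion component, phase-inversion noise estimation, stopping
# rules, and level-function slopes.

DPOAE_FLOOR_DB <- -30  # display floor for noise magnitudes (dB SPL)

amp_to_db_spl <- function(a) {
  20 * log10(pmax(a / sqrt(2), 1e-12) / P_REF)
}

#' Precompute the windowed least-squares frames for a sweep geometry
#'
#' For every analysis frame (Hann window of `window` samples advanced by
#' `step` samples) the sine/cosine regressors along the exact closed-form
#' phase trajectories of the 2f1-f2 distortion component and of the two
#' primaries are built and their weighted normal equations factorized once.
#' The analyzer can then be applied cheaply to any number of recordings that
#' share the sweep geometry.
#'
#' @param sweep A [sweep_pair()] describing the primaries.
#' @param window Window length in samples (default 24000, i.e. 0.5 s at
#'   48 kHz).
#' @param step Frame step in samples (default 600, i.e. 12.5 ms at 48 kHz).
#' @return Object of class `dpoae_analyzer`.
#' @export
dpoae_analyzer <- function(sweep, window = 24000, step = 600) {
  stopifnot(inherits(sweep, "sweep_pair"))
  fs <- sweep$fs_hz
  if (fs != 48000) {
    scale <- fs / 48000
    window <- round(window * scale)
    step <- round(step * scale)
    message("non-48 kHz sweep: window/step rescaled to ", window, "/", step,
            " samples")
  }
  n <- round(sweep$duration_s * fs)
  starts <- seq(1L, n - window + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(window) - 1L) / (window - 1L))
  frames <- vector("list", length(starts))
  f1_0 <- sweep$f2_start_hz / sweep$ratio
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + window - 1L)
    t <- (idx - 1L) / fs
    ph_dp <- dp_phase(sweep, t)
    ph_f1 <- sweep_phase(f1_0, sweep$rate_oct_per_s, t)
    ph_f2 <- sweep_phase(sweep$f2_start_hz, sweep$rate_oct_per_s, t)
    X <- cbind(cos(ph_dp), sin(ph_dp), cos(ph_f1), sin(ph_f1),
               cos(ph_f2), sin(ph_f2))
    WX <- X * w
    xtx <- crossprod(X, WX)
    frames[[i]] <- list(idx = idx, WX = WX, chol = chol(xtx))
  }
  centre <- (starts + (window - 1) / 2 - 1) / fs
  f_at <- sweep_frequencies(sweep, centre)
  structure(list(sweep = sweep, window = window, step = step,
                 frames = frames, frame_times = centre,
                 f2_at_frame = f_at$f2, fdp_at_frame = f_at$fdp),
            class = "dpoae_analyzer")
}

#' Least-squares DPOAE frame series of one recording
#'
#' Per frame, the amplitude and phase of a model sinusoid following the
#' time-varying 2f1-f2 trajectory (with the two primaries as nuisance
#' regressors) are estimated by Hann-weighted least squares. Frames that
#' would extend past the end of the recording are dropped at analyzer
#' construction.
#'
#' @param recording Ear-canal waveform (Pa) at the sweep's sampling rate.
#' @param analyzer A [dpoae_analyzer()] (or a `sweep_pair`, in which case an
#'   analyzer is built on the fly).
#' @return data.frame of class `sweep_frame_series`: `frame_time_s`,
#'   `f2_at_frame_hz`, `fdp_at_frame_hz`, `dp_amplitude_pa`,
#'   `dp_magnitude_db`, `dp_phase_deg`.
#' @export
lsf_frames <- function(recording, analyzer) {
  if (inherits(analyzer, "sweep_pair")) analyzer <- dpoae_analyzer(analyzer)
  stopifnot(inherits(analyzer, "dpoae_analyzer"))
  nfr <- length(analyzer$frames)
  amp <- numeric(nfr); ph <- numeric(nfr)
  for (i in seq_len(nfr)) {
    fr <- analyzer$frames[[i]]
    if (max(fr$idx) > length(recording))
      stop("recording shorter than the sweep geometry")
    b <- crossprod(fr$WX, recording[fr$idx])
    beta <- backsolve(fr$chol, forwardsolve(t(fr$chol), b))
    amp[i] <- sqrt(beta[1]^2 + beta[2]^2)
    ph[i] <- atan2(-beta[2], beta[1]) * 180 / pi
  }
  structure(data.frame(frame_time_s = analyzer$frame_times,
                       f2_at_frame_hz = analyzer$f2_at_frame,
                       fdp_at_frame_hz = analyzer$fdp_at_frame,
                       dp_amplitude_pa = amp,
                       dp_magnitude_db = amp_to_db_spl(amp),
                       dp_phase_deg = ph),
            class = c("sweep_frame_series", "data.frame"))
}

#' Noise frame series from a phase-inverted sweep pair
#'
#' Two consecutive sweep recordings with identical trajectories are averaged
#' after inverting the second one, cancelling deterministic content; the
#' least-squares magnitude of the residual along the distortion-product
#' trajectory is the noise estimate. The signal estimate is the plain
#' average. (The second sweep of a recorded pair is presented with its
#' starting phase inverted by pi, so subtraction of the recorded waveforms
#' realizes the phase inversion.)
#'
#' @param rec_a,rec_b The two recordings of a sweep pair.
#' @param analyzer A [dpoae_analyzer()].
#' @return List with `signal` and `noise` frame series; noise magnitudes are
#'   floored at -30 dB SPL for display (`dp_magnitude_db`), the unfloored
#'   values retained in `dp_magnitude_db_raw`.
#' @export
noise_from_pair <- function(rec_a, rec_b, analyzer) {
  if (length(rec_a) != length(rec_b))
    stop("mismatched sweep recordings (different lengths)")
  sig <- lsf_frames((rec_a + rec_b) / 2, analyzer)
  noi <- lsf_frames((rec_a - rec_b) / 2, analyzer)
  noi$dp_magnitude_db_raw <- noi$dp_magnitude_db
  noi$dp_magnitude_db <- pmax(noi$dp_magnitude_db, DPOAE_FLOOR_DB)
  list(signal = sig, noise = noi)
}

#' Band readout of a DPOAE frame series
#'
#' The per-band DPOAE magnitude is the power-average of the frames whose
#' instantaneous f2 lies within +/- 1/24 octave of the nominal band
#' frequency (single-nearest-frame readout would be noise-prone).
#'
#' @param frames A `sweep_frame_series`.
#' @param bands_hz Nominal f2 frequencies (default 500/1000/2000/4000 Hz).
#' @param half_width_oct Half-width of the readout band in octaves.
#' @return Named numeric vector of band magnitudes in dB SPL.
#' @export
band_readout <- function(frames, bands_hz = c(500, 1000, 2000, 4000),
                         half_width_oct = 1 / 24) {
  vapply(bands_hz, function(b) {
    sel <- abs(log2(frames$f2_at_frame_hz / b)) <= half_width_oct
    if (!any(sel)) return(NA_real_)
    amp_to_db_spl(sqrt(mean(frames$dp_amplitude_pa[sel]^2)))
  }, numeric(1)) |> stats::setNames(paste0(bands_hz, "Hz"))
}

#' DPOAE recording stopping rule
#'
#' Recording stops when the running-average SNR exceeds 10 dB in all four
#' frequency bands of interest, or after 8 pairs of sweeps.
#'
#' @param snr_by_band Numeric vector of running-average band SNRs (dB).
#' @param pairs_done Number of sweep pairs recorded so far.
#' @param snr_stop_db SNR criterion (dB).
#' @param max_pairs Maximum number of pairs.
#' @return `"stop"` or `"continue"`.
#' @export
stopping_rule <- function(snr_by_band, pairs_done, snr_stop_db = 10,
                          max_pairs = 8) {
  if (pairs_done >= max_pairs) return("stop")
  if (all(is.finite(snr_by_band)) && all(snr_by_band > snr_stop_db)) "stop"
  else "continue"
}

#' Analyze a set of DPOAE sweep-pair recordings at one primary level
#'
#' Pairs are consumed in order; after each pair the running averages of the
#' signal and noise recordings are re-analyzed and the stopping rule
#' evaluated. Significance per band requires SNR >= 10 dB.
#'
#' @param pairs List of sweep pairs, each a list with elements `a` and `b`
#'   (the two recordings).
#' @param analyzer A [dpoae_analyzer()].
#' @param level_db_spl Primary level (bookkeeping).
#' @param bands_hz Readout bands.
#' @return data.frame of DPOAE points (one row per band): `band_hz`,
#'   `level_db_spl`, `magnitude_db`, `noise_db`, `snr_db`, `significant`,
#'   plus attribute `pairs_used`.
#' @export
analyze_dpoae_level <- function(pairs, analyzer, level_db_spl = NA_real_,
                                bands_hz = c(500, 1000, 2000, 4000)) {
  sum_sig <- NULL; sum_noi <- NULL
  used <- 0L
  for (p in pairs) {
    sig_rec <- (p$a + p$b) / 2
    noi_rec <- (p$a - p$b) / 2
    sum_sig <- if (is.null(sum_sig)) sig_rec else sum_sig + sig_rec
    sum_noi <- if (is.null(sum_noi)) noi_rec else sum_noi + noi_rec
    used <- used + 1L
    sig <- lsf_frames(sum_sig / used, analyzer)
    noi <- lsf_frames(sum_noi / used, analyzer)
    mag <- band_readout(sig, bands_hz)
    nfl <- band_readout(noi, bands_hz)
    snr <- mag - nfl
    if (stopping_rule(snr, used) == "stop") break
  }
  out <- data.frame(band_hz = bands_hz, level_db_spl = level_db_spl,
                    magnitude_db = unname(mag),
                    noise_db = pmax(unname(nfl), DPOAE_FLOOR_DB),
                    snr_db = unname(snr),
                    significant = unname(snr) >= 10)
  attr(out, "pairs_used") <- used
  out
}

#' DPOAE level-function slope (compression estimate)
#'
#' Ordinary least-squares slope of the statistically significant DPOAE
#' magnitudes against primary level; the slope is the cochlear compression
#' estimate.
#'
#' @param points data.frame of DPOAE points for one band (columns
#'   `level_db_spl`, `magnitude_db`, `significant`).
#' @return A `level_fit` (linear), or `NULL` with fewer than two significant
#'   points.
#' @export
dpoae_slope <- function(points) {
  sig <- points[points$significant, , drop = FALSE]
  if (nrow(sig) < 2) return(NULL)
  fit_linear(sig$level_db_spl, sig$magnitude_db)
}
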