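# EFR analysis chain: epoched EEG -> magnitude-level functions with
# significance flags, noise floors and latencies.

#' Epoched EEG recording container
#'
#' Holds 1-s multichannel EEG epochs aligned to stimulus triggers.
#'
#' @param epochs Numeric array `n_epochs x n_samples x n_channels`, or an
#'   `n_epochs x n_samples` matrix for a single channel. Each epoch must span
#'   exactly one second at `fs_hz`.
#' @param fs_hz Stored sampling rate in Hz.
#' @param channel_labels Character vector of channel names.
#' @param level_db_spl Per-component stimulus level of the run (dB SPL).
#' @return Object of class `epoched_recording`.
#' @export
epoched_recording <- function(epochs, fs_hz, channel_labels = NULL,
                              level_db_spl = NA_real_) {
  if (is.matrix(epochs)) dim(epochs) <- c(dim(epochs), 1L)
  stopifnot(length(dim(epochs)) == 3L)
  if (dim(epochs)[2] != round(fs_hz))
    stop("each epoch must contain exactly 1 s of samples (", round(fs_hz),
         " at fs = ", fs_hz, " Hz), got ", dim(epochs)[2])
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(dim(epochs)[3]))
  structure(list(epochs = epochs, fs_hz = fs_hz,
                 channel_labels = channel_labels,
                 trigger_index = seq_len(dim(epochs)[1]),
                 level_db_spl = level_db_spl),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat(sprintf("<epoched_recording> %d epochs x %d samples x %d channel(s), fs = %g Hz, level = %g dB SPL\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$fs_hz, x$level_db_spl))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filtering of epoched EEG
#'
#' A fourth-order Butterworth band-pass (default corners 60 and 400 Hz) is
#' applied forward and backward (`signal::filtfilt`) to every epoch and
#' channel, giving zero net phase shift and the squared magnitude response.
#'
#' @param rec An `epoched_recording`.
#' @param lo,hi Corner frequencies in Hz.
#' @param order Filter order of the single-pass prototype.
#' @return Filtered `epoched_recording`.
#' @export
bandpass_zero_phase <- function(rec, lo = 60, hi = 400, order = 4) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (rec$fs_hz <= 2 * hi)
    stop("sampling rate too low for the requested upper corner")
  bf <- signal::butter(order, c(lo, hi) / (rec$fs_hz / 2), type = "pass")
  d <- dim(rec$epochs)
  for (ch in seq_len(d[3])) {
    for (ep in seq_len(d[1])) {
      rec$epochs[ep, , ch] <- signal::filtfilt(bf, rec$epochs[ep, , ch])
    }
  }
  rec
}

#' Reject epochs exceeding a voltage threshold
#'
#' Epochs whose maximum absolute amplitude exceeds `threshold_uv` on any
#' channel are removed; surviving epochs keep their acquisition order.
#'
#' @param rec An `epoched_recording` (already filtered; rejection operates on
#'   the filtered signal).
#' @param threshold_uv Rejection threshold in microvolts.
#' @return The surviving `epoched_recording`, with attributes
#'   `n_rejected` and `rejected_index`.
#' @export
reject_artifacts <- function(rec, threshold_uv = 80) {
  stopifnot(inherits(rec, "epoched_recording"))
  peak <- apply(abs(rec$epochs), 1, max)
  keep <- peak <= threshold_uv
  if (!any(keep))
    stop("all epochs rejected at threshold ", threshold_uv, " uV")
  out <- rec
  out$epochs <- rec$epochs[keep, , , drop = FALSE]
  out$trigger_index <- rec$trigger_index[keep]
  attr(out, "n_rejected") <- sum(!keep)
  attr(out, "rejected_index") <- which(!keep)
  out
}

#' Concatenate surviving epochs into 16-s trials
#'
#' Epochs are concatenated in acquisition order, `epochs_per_trial` at a time,
#' to raise the spectral resolution to `1/epochs_per_trial` Hz. Leftover
#' epochs that do not fill a trial are discarded.
#'
#' @param rec An `epoched_recording` (single channel is used; see `channel`).
#' @param epochs_per_trial Number of 1-s epochs per trial (default 16).
#' @param channel Channel index or label to analyze.
#' @return List with `trials` (matrix `n_trials x (epochs_per_trial*fs)`),
#'   `epoch_variances` (matrix `n_trials x epochs_per_trial`), `fs_hz`,
#'   `n_discarded`.
#' @export
form_trials <- function(rec, epochs_per_trial = 16, channel = 1) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (is.character(channel)) channel <- match(channel, rec$channel_labels)
  n <- dim(rec$epochs)[1]
  if (n < epochs_per_trial)
    stop("need at least ", epochs_per_trial, " surviving epochs, have ", n)
  ns <- dim(rec$epochs)[2]
  n_trials <- n %/% epochs_per_trial
  trials <- matrix(0, n_trials, epochs_per_trial * ns)
  vars <- matrix(0, n_trials, epochs_per_trial)
  for (tr in seq_len(n_trials)) {
    for (k in seq_len(epochs_per_trial)) {
      e <- rec$epochs[(tr - 1L) * epochs_per_trial + k, , channel]
      trials[tr, ((k - 1L) * ns + 1L):(k * ns)] <- e
      vars[tr, k] <- stats::var(e)
    }
  }
  list(trials = trials, epoch_variances = vars, fs_hz = rec$fs_hz,
       n_discarded = n - n_trials * epochs_per_trial)
}

#' Inverse-variance weighted ensemble average of trials
#'
#' For each 1-s epoch position within the trial frame, the average across
#' trials is the inverse-variance-weighted mean of the corresponding epochs,
#' with weights normalized to sum to one per position.
#'
#' @param trials Matrix `n_trials x n_samples` from [form_trials()].
#' @param epoch_variances Matrix `n_trials x epochs_per_trial` of per-epoch
#'   variances.
#' @return Averaged waveform (length `n_samples`).
#' @export
weighted_average <- function(trials, epoch_variances) {
  if (any(epoch_variances <= 0))
    stop("zero or negative epoch variance gives a degenerate weight")
  n_pos <- ncol(epoch_variances)
  ns <- ncol(trials) / n_pos
  out <- numeric(ncol(trials))
  w <- 1 / epoch_variances
  for (k in seq_len(n_pos)) {
    wk <- w[, k] / sum(w[, k])
    idx <- ((k - 1L) * ns + 1L):(k * ns)
    out[idx] <- as.numeric(crossprod(trials[, idx, drop = FALSE], wk))
  }
  out
}

#' Amplitude spectrum of an averaged trial waveform
#'
#' @param x Averaged waveform.
#' @param fs_hz Sampling rate.
#' @return List with `freq_hz`, `amplitude` (single-sided, `2|X|/N`),
#'   `phase_deg`, `resolution_hz`.
#' @export
amplitude_spectrum <- function(x, fs_hz) {
  n <- length(x)
  X <- stats::fft(x)
  half <- seq_len(floor(n / 2) + 1L)
  amp <- 2 * Mod(X[half]) / n
  amp[1] <- amp[1] / 2
  list(freq_hz = (half - 1L) * fs_hz / n,
       amplitude = amp,
       phase_deg = Arg(X[half]) * 180 / pi,
       resolution_hz = fs_hz / n)
}

#' Spectral F-test for a response at the modulation frequency
#'
#' The F-ratio is the power in the modulation-frequency bin divided by the
#' mean power of the bins within `half_width_hz` below and above it (96 bins
#' at a spectral resolution of 1/16 Hz). The p-value is `1 - F_cdf(ratio)`
#' with 2 and `n_noise_bins` degrees of freedom; significance requires
#' `p <= alpha`. Noise bins that fall on other stimulus modulation
#' frequencies can be excluded via `exclude_hz`.
#'
#' @param spec Spectrum from [amplitude_spectrum()].
#' @param modulation_hz Modulation frequency; must fall on an exact bin.
#' @param half_width_hz Half-width of the noise neighborhood in Hz.
#' @param alpha Significance level.
#' @param exclude_hz Frequencies (Hz) whose bins must not be used as noise
#'   bins (e.g. the other carriers' modulation frequencies).
#' @return List with `f_ratio`, `p_value`, `significant`, `noise_floor_db`
#'   (dB of the mean noise-bin amplitude), `n_noise_bins`, `n_excluded`.
#' @export
f_test <- function(spec, modulation_hz, half_width_hz = 3, alpha = 0.01,
                   exclude_hz = numeric(0)) {
  res <- spec$resolution_hz
  k <- modulation_hz / res
  if (abs(k - round(k)) > 1e-9)
    stop("modulation frequency does not fall on an exact spectral bin")
  k <- as.integer(round(k)) + 1L  # 1-based index of the signal bin
  hw <- as.integer(round(half_width_hz / res))
  nb <- c((k - hw):(k - 1L), (k + 1L):(k + hw))
  nb <- nb[nb >= 2L & nb <= length(spec$amplitude)]
  excl <- as.integer(round(exclude_hz / res)) + 1L
  n_excluded <- sum(nb %in% excl)
  nb <- setdiff(nb, excl)
  p_sig <- spec$amplitude[k]^2
  p_noise <- mean(spec$amplitude[nb]^2)
  f_ratio <- p_sig / p_noise
  p_value <- stats::pf(f_ratio, 2, length(nb), lower.tail = FALSE)
  list(f_ratio = f_ratio, p_value = p_value,
       significant = p_value <= alpha,
       noise_floor_db = 20 * log10(mean(spec$amplitude[nb])),
       n_noise_bins = length(nb), n_excluded = n_excluded)
}

#' EFR readout at one modulation frequency
#'
#' Reads magnitude (dB re 1 uV) and phase from the spectrum of the averaged
#' waveform at the modulation-frequency bin, together with the F-test result.
#'
#' @param avg Averaged waveform from [weighted_average()].
#' @param fs_hz Sampling rate.
#' @param modulation_hz Modulation frequency (must be an exact bin).
#' @param carrier_hz Carrier frequency (bookkeeping only).
#' @param level_db_spl Stimulus level (bookkeeping only).
#' @param ... Passed to [f_test()].
#' @return One-row data.frame (an "EFR point") with columns `carrier_hz`,
#'   `modulation_hz`, `level_db_spl`, `magnitude_db`, `phase_deg`, `f_ratio`,
#'   `p_value`, `significant`, `noise_floor_db`.
#' @export
efr_from_spectrum <- function(avg, fs_hz, modulation_hz, carrier_hz = NA_real_,
                              level_db_spl = NA_real_, ...) {
  spec <- amplitude_spectrum(avg, fs_hz)
  k <- modulation_hz / spec$resolution_hz
  if (abs(k - round(k)) > 1e-9)
    stop("modulation frequency does not fall on an exact spectral bin")
  k <- as.integer(round(k)) + 1L
  ft <- f_test(spec, modulation_hz, ...)
  data.frame(carrier_hz = carrier_hz, modulation_hz = modulation_hz,
             level_db_spl = level_db_spl,
             magnitude_db = 20 * log10(spec$amplitude[k]),
             phase_deg = spec$phase_deg[k],
             f_ratio = ft$f_ratio, p_value = ft$p_value,
             significant = ft$significant,
             noise_floor_db = ft$noise_floor_db)
}

#' Convert an EFR phase series to latency increments
#'
#' Phases (degrees, one per stimulus level, increasing level order) are
#' unwrapped across levels, delayed by 90 degrees to compensate the sine
#' starting phase of the stimulus envelope, and converted to latency by
#' dividing by `360 * fm`. Because absolute phase is ambiguous, the result is
#' reported as the increment over the series minimum. Non-significant points
#' (`NA` phase) are excluded from unwrapping and returned as `NA`.
#'
#' @param phase_deg Numeric vector of phases in degrees (NA = missing).
#' @param modulation_hz Modulation frequency in Hz.
#' @return Numeric vector of latency increments in ms (NA preserved).
#' @export
phase_to_latency <- function(phase_deg, modulation_hz) {
  ok <- !is.na(phase_deg)
  out <- rep(NA_real_, length(phase_deg))
  if (!any(ok)) return(out)
  ph <- phase_deg[ok] * pi / 180
  ph <- as.numeric(unwrap_phase(ph)) * 180 / pi
  latency_ms <- -(ph + 90) / (360 * modulation_hz) * 1000
  out[ok] <- latency_ms - min(latency_ms)
  out
}

# Phase unwrapping (radians): removes 2*pi jumps between consecutive values.
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

#' Analyze one epoched EEG run into EFR points for all carriers
#'
#' Runs the full chain (band-pass filter, artifact rejection, trial
#' formation, inverse-variance weighted averaging, spectral readout with
#' F-test) for each carrier/modulation pair of the stimulus.
#'
#' @param rec An `epoched_recording` for one stimulus level.
#' @param config An [analysis_config()].
#' @return data.frame of EFR points (one row per carrier), with attributes
#'   `n_rejected` and `n_trials`.
#' @export
analyze_efr_run <- function(rec, config = analysis_config()) {
  filt <- bandpass_zero_phase(rec, config$filter_lo_hz, config$filter_hi_hz,
                              config$filter_order)
  kept <- reject_artifacts(filt, config$reject_threshold_uv)
  tri <- form_trials(kept, config$epochs_per_trial, config$channel)
  avg <- weighted_average(tri$trials, tri$epoch_variances)
  rows <- lapply(seq_along(config$carriers_hz), function(i) {
    efr_from_spectrum(avg, rec$fs_hz, config$modulations_hz[i],
                      carrier_hz = config$carriers_hz[i],
                      level_db_spl = rec$level_db_spl,
                      half_width_hz = config$f_test_half_width_hz,
                      alpha = config$f_test_alpha,
                      exclude_hz = setdiff(config$modulations_hz,
                                           config$modulations_hz[i]))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_rejected") <- attr(kept, "n_rejected")
  attr(out, "n_trials") <- nrow(tri$trials)
  out
}

#' Analyze a session of runs into magnitude-level functions
#'
#' @param recordings List of `epoched_recording` objects, one per stimulus
#'   level.
#' @param config An [analysis_config()].
#' @return Object of class `efr_session`: a list of per-carrier
#'   `magnitude_level_function` data.frames (points ordered by level, with a
#'   `delta_latency_ms` column computed from significant phases).
#' @export
analyze_efr_session <- function(recordings, config = analysis_config()) {
  pts <- do.call(rbind, lapply(recordings, analyze_efr_run, config = config))
  per_carrier <- lapply(config$carriers_hz, function(fc) {
    d <- pts[pts$carrier_hz == fc, , drop = FALSE]
    d <- d[order(d$level_db_spl), , drop = FALSE]
    if (anyDuplicated(d$level_db_spl))
      stop("duplicate stimulus levels for carrier ", fc)
    ph <- ifelse(d$significant, d$phase_deg, NA_real_)
    d$delta_latency_ms <- phase_to_latency(ph, d$modulation_hz[1])
    class(d) <- c("magnitude_level_function", "data.frame")
    d
  })
  names(per_carrier) <- paste0(config$carriers_hz, "Hz")
  structure(per_carrier, class = "efr_session")
}

#' Plot a magnitude-level function
#' @param x A `magnitude_level_function`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.magnitude_level_function <- function(x, ...) {
  graphics::plot(x$level_db_spl, x$magnitude_db,
                 pch = ifelse(x$significant, 19, 1),
                 xlab = "Stimulus level (dB SPL)",
                 ylab = "EFR magnitude (dB re 1 uV)", ...)
  graphics::lines(x$level_db_spl, x$noise_floor_db, lty = 3, col = "grey40")
}
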