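# Stimulus synthesis: calibrated SAM-tone complexes and swept DPOAE primaries.

P_REF <- 20e-6  # reference pressure, Pa (0 dB SPL)

#' SAM tone component description
#'
#' Describes one sinusoidally amplitude-modulated (SAM) tone: a sine carrier
#' at `carrier_hz` whose envelope is `1 + m * sin(2*pi*fm*t)`, calibrated to a
#' root-mean-square sound pressure level in dB SPL (re 20 uPa).
#'
#' @param carrier_hz Carrier frequency in Hz.
#' @param modulation_hz Modulation frequency in Hz; must be below the carrier.
#' @param modulation_depth Modulation depth m, a fraction in [0, 1].
#' @param level_db_spl RMS level of the calibrated component in dB SPL.
#' @param start_phase Carrier/modulator start phase in radians (sine
#'   convention: 0 means both start as `sin`).
#' @return An object of class `sam_component`.
#' @export
sam_component <- function(carrier_hz, modulation_hz, modulation_depth = 0.85,
                          level_db_spl = 60, start_phase = 0) {
  stopifnot(is.finite(carrier_hz), is.finite(modulation_hz),
            is.finite(level_db_spl), is.finite(start_phase))
  if (modulation_hz >= carrier_hz)
    stop("modulation frequency must be below the carrier frequency")
  if (modulation_depth < 0 || modulation_depth > 1)
    stop("modulation depth must lie in [0, 1]")
  structure(list(carrier_hz = carrier_hz, modulation_hz = modulation_hz,
                 modulation_depth = modulation_depth,
                 level_db_spl = level_db_spl, start_phase = start_phase),
            class = "sam_component")
}

#' Default four-component SAM complex
#'
#' The multi-frequency stimulus used throughout: carriers 498, 1000, 2005 and
#' 4011 Hz, modulated at 81, 87, 93 and 98 Hz respectively, 85 % modulation
#' depth, each component individually calibrated to `level_db_spl`.
#'
#' @param level_db_spl Per-component level in dB SPL.
#' @return List of four `sam_component` objects.
#' @export
default_sam_components <- function(level_db_spl = 60) {
  fc <- c(498, 1000, 2005, 4011)
  fm <- c(81, 87, 93, 98)
  Map(function(c., m.) sam_component(c., m., 0.85, level_db_spl), fc, fm)
}

#' Synthesize one calibrated SAM tone
#'
#' The waveform is `A * (1 + m sin(2 pi fm t + phi)) * sin(2 pi fc t + phi)`,
#' scaled so that its RMS pressure equals `20e-6 * 10^(level/20)` Pa.
#'
#' @param c A `sam_component`.
#' @param duration_s Duration in seconds (> 0).
#' @param fs_hz Sampling rate in Hz; must exceed twice the highest component
#'   frequency (carrier + modulation).
#' @return Numeric pressure waveform in Pa.
#' @export
make_sam_tone <- function(c, duration_s, fs_hz = 48000) {
  stopifnot(inherits(c, "sam_component"))
  if (duration_s <= 0) stop("duration must be positive")
  if (fs_hz <= 2 * (c$carrier_hz + c$modulation_hz))
    stop("sampling rate too low for this component (aliasing)")
  n <- round(duration_s * fs_hz)
  t <- (seq_len(n) - 1L) / fs_hz
  env <- 1 + c$modulation_depth * sin(2 * pi * c$modulation_hz * t + c$start_phase)
  x <- env * sin(2 * pi * c$carrier_hz * t + c$start_phase)
  target_rms <- P_REF * 10^(c$level_db_spl / 20)
  x * target_rms / sqrt(mean(x^2))
}

#' Synthesize a multi-component SAM complex
#'
#' Components are calibrated individually and then summed sample-wise, so the
#' overall level of k equal-level components with distinct frequencies is
#' about `10*log10(k)` dB above a single component (+6 dB for four).
#'
#' @param components List of `sam_component` objects with distinct modulation
#'   frequencies.
#' @inheritParams make_sam_tone
#' @return Numeric pressure waveform in Pa.
#' @export
make_multi_sam <- function(components, duration_s, fs_hz = 48000) {
  fm <- vapply(components, function(c) c$modulation_hz, numeric(1))
  if (anyDuplicated(fm))
    stop("duplicate modulation frequencies: spectral readout bins would collide")
  Reduce(`+`, lapply(components, make_sam_tone, duration_s = duration_s,
                     fs_hz = fs_hz))
}

#' Measure the level of a pressure waveform
#' @param x Pressure waveform in Pa.
#' @return RMS level in dB SPL.
#' @export
db_spl <- function(x) 20 * log10(sqrt(mean(x^2)) / P_REF)

#' Swept DPOAE primary pair description
#'
#' Two upward exponential (log-frequency) sweeps of equal level: `f2` runs
#' from `f2_start_hz` to `f2_end_hz` at `rate_oct_per_s` octaves per second
#' while `f1(t) = f2(t) / ratio`. The sweep duration is implied:
#' `log2(f2_end/f2_start) / rate`.
#'
#' @param f2_start_hz,f2_end_hz Start and end f2 frequencies (Hz).
#' @param ratio Primary frequency ratio f2/f1 (> 1), default 1.22.
#' @param rate_oct_per_s Sweep rate in octaves/second (> 0), default 0.5.
#' @param level_db_spl Per-primary level in dB SPL.
#' @param fs_hz Sampling rate, default 48 kHz.
#' @return An object of class `sweep_pair`.
#' @export
sweep_pair <- function(f2_start_hz = 250, f2_end_hz = 8000, ratio = 1.22,
                       rate_oct_per_s = 0.5, level_db_spl = 60, fs_hz = 48000) {
  if (ratio <= 1) stop("ratio f2/f1 must exceed 1")
  if (f2_end_hz <= f2_start_hz) stop("f2_end must exceed f2_start")
  if (rate_oct_per_s <= 0) stop("sweep rate must be positive")
  structure(list(f2_start_hz = f2_start_hz, f2_end_hz = f2_end_hz,
                 ratio = ratio, rate_oct_per_s = rate_oct_per_s,
                 level_db_spl = level_db_spl, fs_hz = fs_hz,
                 duration_s = log2(f2_end_hz / f2_start_hz) / rate_oct_per_s),
            class = "sweep_pair")
}

#' Instantaneous frequencies along a sweep
#' @param p A `sweep_pair`.
#' @param t Time in seconds.
#' @return List with elements `f1`, `f2`, `fdp` (= 2 f1 - f2) in Hz.
#' @export
sweep_frequencies <- function(p, t) {
  f2 <- p$f2_start_hz * 2^(p$rate_oct_per_s * t)
  f1 <- f2 / p$ratio
  list(f1 = f1, f2 = f2, fdp = 2 * f1 - f2)
}

# Closed-form phase (radians) of an exponential sweep that starts at f0 Hz:
# phi(t) = 2*pi * f0 * (2^(r t) - 1) / (r * log(2)).  Using the analytic
# integral of the instantaneous frequency avoids cumulative-sum phase drift.
sweep_phase <- function(f0, rate_oct_per_s, t) {
  2 * pi * f0 * (2^(rate_oct_per_s * t) - 1) / (rate_oct_per_s * log(2))
}

#' Phase trajectory of the 2f1-f2 distortion component
#' @inheritParams sweep_frequencies
#' @return Phase in radians at times `t`.
#' @export
dp_phase <- function(p, t) {
  f1_0 <- p$f2_start_hz / p$ratio
  2 * sweep_phase(f1_0, p$rate_oct_per_s, t) -
    sweep_phase(p$f2_start_hz, p$rate_oct_per_s, t)
}

#' Synthesize the two swept primaries
#'
#' Each primary is an exponential sweep calibrated to `level_db_spl` RMS.
#'
#' @param p A `sweep_pair`.
#' @return List with `f1`, `f2` waveforms (Pa), `fs_hz` and `duration_s`.
#' @export
make_dpoae_sweep_pair <- function(p) {
  stopifnot(inherits(p, "sweep_pair"))
  n <- round(p$duration_s * p$fs_hz)
  t <- (seq_len(n) - 1L) / p$fs_hz
  amp <- sqrt(2) * P_REF * 10^(p$level_db_spl / 20)
  w1 <- amp * sin(sweep_phase(p$f2_start_hz / p$ratio, p$rate_oct_per_s, t))
  w2 <- amp * sin(sweep_phase(p$f2_start_hz, p$rate_oct_per_s, t))
  list(f1 = w1, f2 = w2, fs_hz = p$fs_hz, duration_s = p$duration_s)
}

#' Write a waveform to WAV with a JSON metadata sidecar
#'
#' Float WAV (32-bit) written without external dependencies; metadata (sampling
#' rate plus any stimulus parameters supplied) goes to `<file>.json`.
#'
#' @param x Numeric waveform.
#' @param file Output path ending in `.wav`.
#' @param fs_hz Sampling rate.
#' @param meta Optional list of metadata stored in the sidecar.
#' @return `file`, invisibly.
#' @export
write_wav_float <- function(x, file, fs_hz, meta = list()) {
  con <- file(file, "wb")
  on.exit(close(con))
  n <- length(x)
  data_bytes <- n * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(fs_hz), con, size = 4, endian = "little")
  writeBin(as.integer(fs_hz * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  sidecar <- c(list(fs_hz = fs_hz, n_samples = n), meta)
  jsonlite::write_json(sidecar, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' Read a float WAV written by [write_wav_float()]
#' @param file Path to the WAV file.
#' @return List with `x` (waveform) and `fs_hz`.
#' @export
read_wav_float <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (hdr != "RIFF") stop("not a RIFF/WAV file: ", file)
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  readChar(con, 8)
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
  fs <- readBin(con, integer(), 1, size = 4, endian = "little")
  readBin(con, integer(), 1, size = 4, endian = "little")
  readBin(con, integer(), 2, size = 2, endian = "little")
  readChar(con, 4)
  nb <- readBin(con, integer(), 1, size = 4, endian = "little")
  x <- readBin(con, numeric(), nb / 4, size = 4, endian = "little")
  list(x = x, fs_hz = fs, channels = fmt[2])
}
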