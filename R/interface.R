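# Analysis configuration, JSON round-tripping, provenance records, and
# high-level pipeline glue.

#' Analysis configuration
#'
#' Bundles every tunable of the EFR recording pipeline in one validated
#' object so that a session analysis is fully described by its
#' configuration.
#'
#' @param channel Channel index or label to analyze.
#' @param filter_lo_hz,filter_hi_hz Band-pass corner frequencies.
#' @param filter_order Butterworth order of the single-pass prototype.
#' @param reject_threshold_uv Epoch rejection threshold (uV peak).
#' @param epochs_per_trial Epochs concatenated per trial.
#' @param carriers_hz,modulations_hz Stimulus carrier and modulation
#'   frequencies (paired, no duplicate modulations).
#' @param f_test_alpha Significance level of the spectral F-test.
#' @param f_test_half_width_hz Noise-neighborhood half-width (Hz).
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(channel = 1,
                            filter_lo_hz = 60, filter_hi_hz = 400,
                            filter_order = 4,
                            reject_threshold_uv = 80,
                            epochs_per_trial = 16,
                            carriers_hz = c(498, 1000, 2005, 4011),
                            modulations_hz = c(81, 87, 93, 98),
                            f_test_alpha = 0.01,
                            f_test_half_width_hz = 3) {
  stopifnot(filter_lo_hz > 0, filter_hi_hz > filter_lo_hz,
            filter_order >= 1, reject_threshold_uv > 0,
            epochs_per_trial >= 1,
            length(carriers_hz) == length(modulations_hz),
            !anyDuplicated(modulations_hz),
            f_test_alpha > 0, f_test_alpha < 1,
            f_test_half_width_hz > 0)
  structure(list(channel = channel,
                 filter_lo_hz = filter_lo_hz, filter_hi_hz = filter_hi_hz,
                 filter_order = filter_order,
                 reject_threshold_uv = reject_threshold_uv,
                 epochs_per_trial = epochs_per_trial,
                 carriers_hz = carriers_hz, modulations_hz = modulations_hz,
                 f_test_alpha = f_test_alpha,
                 f_test_half_width_hz = f_test_half_width_hz),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf("<analysis_config> ch %s, band %g-%g Hz (order %d), reject %g uV, %d epochs/trial, alpha %g\n",
              as.character(x$channel), x$filter_lo_hz, x$filter_hi_hz,
              x$filter_order, x$reject_threshold_uv, x$epochs_per_trial,
              x$f_test_alpha))
  invisible(x)
}

#' Write an analysis configuration to JSON
#' @param config An [analysis_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an analysis configuration from JSON
#' @param path JSON file written by [write_config()].
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, x)
}

#' Provenance record for an analysis
#'
#' Captures package version, R version, timestamp and a digest of the
#' configuration so that results can be traced to the exact settings that
#' produced them.
#'
#' @param config An [analysis_config()].
#' @param seed Optional RNG seed used by the run.
#' @return List of class `provenance`.
#' @export
provenance <- function(config = analysis_config(), seed = NULL) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_config(config, tf)
  structure(list(package = "efrcomp",
                 package_version = as.character(utils::packageVersion("efrcomp")),
                 r_version = as.character(getRversion()),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 config_md5 = unname(tools::md5sum(tf)),
                 seed = seed),
            class = "provenance")
}

#' Run the full EFR session pipeline and fit level functions
#'
#' Analyzes a list of epoched recordings into per-carrier magnitude-level
#' functions, fits each with the two-slope/linear model selection, and
#' returns compression-slope estimates alongside the fitted objects and a
#' provenance record.
#'
#' @param recordings List of [epoched_recording()] objects (one per level).
#' @param config An [analysis_config()].
#' @param seed Optional seed recorded in the provenance (the analysis itself
#'   is deterministic).
#' @return List of class `efr_pipeline_result` with `session` (the
#'   [analyze_efr_session()] output), `fits` (per-carrier `level_fit` or
#'   `NULL`), `slopes` (data.frame `carrier_hz`, `compression_slope`,
#'   `model`, `n_significant`), `provenance`.
#' @export
run_efr_pipeline <- function(recordings, config = analysis_config(),
                             seed = NULL) {
  session <- analyze_efr_session(recordings, config)
  fits <- lapply(session, fit_magnitude_level_function)
  slopes <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(carrier_hz = config$carriers_hz[i],
               compression_slope = if (is.null(f)) NA_real_
                                   else compression_slope(f, "lower"),
               model = if (is.null(f)) NA_character_ else f$model_kind,
               n_significant = sum(session[[i]]$significant))
  }))
  structure(list(session = session, fits = fits, slopes = slopes,
                 provenance = provenance(config, seed)),
            class = "efr_pipeline_result")
}

#' @export
print.efr_pipeline_result <- function(x, ...) {
  cat("<efr_pipeline_result>\n")
  print(x$slopes)
  invisible(x)
}

#' Run the full DPOAE session pipeline and fit level functions
#'
#' @param session List of per-level recordings as produced by
#'   [gen_dpoae_session()] (elements `level_db_spl`, `pairs`, `sweep`).
#' @param analyzer Optional prebuilt [dpoae_analyzer()]; built from the first
#'   level's sweep geometry otherwise.
#' @return List of class `dpoae_pipeline_result` with `points` (all DPOAE
#'   points), `fits` and `slopes` per band.
#' @export
run_dpoae_pipeline <- function(session, analyzer = NULL) {
  if (is.null(analyzer)) analyzer <- dpoae_analyzer(session[[1]]$sweep)
  pts <- do.call(rbind, lapply(session, function(lev) {
    analyze_dpoae_level(lev$pairs, analyzer, lev$level_db_spl)
  }))
  bands <- sort(unique(pts$band_hz))
  fits <- lapply(bands, function(b) {
    dpoae_slope(pts[pts$band_hz == b, , drop = FALSE])
  })
  names(fits) <- paste0(bands, "Hz")
  slopes <- data.frame(
    band_hz = bands,
    slope = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$s,
                   numeric(1)),
    n_significant = vapply(bands, function(b) {
      sum(pts$significant[pts$band_hz == b])
    }, numeric(1)))
  structure(list(points = pts, fits = fits, slopes = slopes),
            class = "dpoae_pipeline_result")
}

#' @export
print.dpoae_pipeline_result <- function(x, ...) {
  cat("<dpoae_pipeline_result>\n")
  print(x$slopes)
  invisible(x)
}
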