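# Shared helpers for the test suite.

# Small epoched recording with a planted sinusoid at `fm` Hz on channel 1,
# white Gaussian noise everywhere, 1-s epochs at `fs` Hz.
make_test_recording <- function(n_epochs = 16, fs = 1024, fm = 98,
                                amp_uv = 1, noise_sd = 0.2,
                                level_db_spl = 60, n_channels = 1,
                                seed = 1) {
  set.seed(seed)
  t <- (seq_len(fs) - 1) / fs
  ep <- array(rnorm(n_epochs * fs * n_channels, 0, noise_sd),
              c(n_epochs, fs, n_channels))
  for (ie in seq_len(n_epochs))
    ep[ie, , 1] <- ep[ie, , 1] + amp_uv * sin(2 * pi * fm * t)
  epoched_recording(ep, fs, level_db_spl = level_db_spl)
}

# Analysis configuration scaled to the 1024 Hz test recordings.
test_config <- function(...) {
  analysis_config(filter_hi_hz = 400, ...)
}
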