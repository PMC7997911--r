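# efrcomp

Estimating peripheral (cochlear) compression from scalp-recorded envelope
following responses (EFRs) and distortion-product otoacoustic emissions
(DPOAEs), with an auditory-nerve population simulation that shows what the
EFR-based estimate actually measures.

## Background

Healthy cochleae amplify soft sounds and compress intense ones: on the
basilar membrane, response magnitude near a fiber's characteristic frequency
(CF) grows at roughly 0.2–0.3 dB per dB of stimulus level over the mid-level
range. Losing this compression (through outer-hair-cell dysfunction) is a
core component of sensorineural hearing loss, so a non-invasive estimate of
compression is clinically interesting.

This package implements two such estimates and one model-based critique:

* **EFR magnitude–level functions.** A multi-frequency sinusoidally
  amplitude-modulated (SAM) tone complex (carriers 498/1000/2005/4011 Hz,
  modulators 81/87/93/98 Hz) is presented over a range of levels while EEG is
  recorded. The EFR magnitude at each modulation frequency, read from the
  spectrum of averaged 16-s trials with a spectral F-test for significance,
  grows with stimulus level; the slope of that growth (dB/dB) is the
  compression estimate.
* **Swept DPOAEs.** Two primaries swept at 0.5 oct/s (f2/f1 = 1.22) evoke the
  2f1−f2 distortion product, extracted per analysis frame by Hann-windowed
  least squares along the closed-form phase trajectory, with a
  phase-inversion noise estimate and an SNR-based stopping rule. The slope of
  DPOAE magnitude against primary level is the otoacoustic compression
  estimate.
* **Auditory-nerve (AN) population model.** An expected-rate phenomenological
  model (middle ear → two-path compressive basilar-membrane stage →
  inner-hair-cell transduction → adapting three-class synapse, 32,000 fibers
  over a log CF grid) simulates the summed AN response to the same stimulus.
  Decomposing the simulated EFR into on-CF and off-CF contributions shows
  that at higher stimulus levels the scalp EFR is dominated by off-CF (tail)
  excitation, so the EFR slope tracks a mixture of compressive and linear
  growth rather than pure on-CF basilar-membrane compression. Impairment
  scenarios (OHC-only, IHC-only, mixed audiogram fits, uniform cochlear
  synaptopathy) separate how each pathology reshapes the level function.

Everything is driven by seeded synthetic-data generators with known ground
truth, so the full analysis chain is testable end to end without any
recordings.

## Worked example

```r
library(efrcomp)

## EFR arm: synthesize a session, run the pipeline
truth <- eeg_truth(noise_psd_uv2hz = 0.02)
session <- gen_eeg_session(truth, levels_db_spl = seq(35, 80, 5),
                           fs = 1024, seed = 7, epochs_per_level = 48)
efr <- run_efr_pipeline(session, analysis_config(), seed = 7)
print(efr)
#> <efr_pipeline_result>
#>   carrier_hz compression_slope     model n_significant
#> 1        498         0.2607122 two_slope            10
#> 2       1000         0.3032194 two_slope            10
#> 3       2005         0.2385115 two_slope            10
#> 4       4011         0.2115695    linear            10

## one fitted level function in detail
print(efr$fits[["4011Hz"]])
#> <level_fit linear> s = 0.212 dB/dB, intercept = -15.5 dB, adj R2 = 0.996, n = 10
```

The planted truth was 0.24/0.31/0.27/0.21 dB/dB for the lower-segment slopes
of the four carriers; the pipeline recovers 0.26/0.30/0.24/0.21 from raw
epoched "EEG".

```r
## DPOAE arm
dp_session <- gen_dpoae_session(dpoae_truth(), seed = 7)
dpoae <- run_dpoae_pipeline(dp_session)
print(dpoae)
#> <dpoae_pipeline_result>
#>        band_hz     slope n_significant
#> 500Hz      500 0.4994310             8
#> 1000Hz    1000 0.7388700             8
#> 2000Hz    2000 0.4454772             8
#> 4000Hz    4000 0.7192323             8
```

Planted DPOAE slopes were 0.50/0.74/0.44/0.72 dB/dB.

```r
## AN simulation (reduced CF grid for the example)
params <- cochlear_parameters(n_cf = 60)
res <- simulate_efr_an(params)
for (scope in c("all_cf", "on_cf", "off_cf")) {
  sl <- fit_efr_an_slope(efr_an_level_function(res, 4011, scope))
  cat(sprintf("4 kHz %-7s slope: %+.3f dB/dB\n", scope, sl$slope))
}
#> 4 kHz all_cf  slope: +0.192 dB/dB
#> 4 kHz on_cf   slope: -0.102 dB/dB
#> 4 kHz off_cf  slope: +0.210 dB/dB
```

The summed (all-CF) compression slope at 4 kHz is close to the off-CF slope
and far from the on-CF slope, which is the model's central point: at the
levels where the slope is measured, off-CF fibers dominate the summed
response. `scenario_suite()` runs the full impairment comparison and
`plot_efr_an_heatmap()` shows the underlying CF × level excitation pattern.

## Package layout

| Module | Contents |
| --- | --- |
| `R/stimuli.R` | Calibrated SAM complexes, swept DPOAE primaries, float WAV I/O |
| `R/efr-pipeline.R` | Filtering, artifact rejection, weighted averaging, F-test, latency |
| `R/level-fit.R` | Constrained two-segment / linear level-function fits |
| `R/dpoae-pipeline.R` | Windowed least-squares DPOAE extraction, noise, stopping rule |
| `R/an-model.R` | Middle ear, two-path BM stage, IHC, synapse, population response |
| `R/efr-an.R` | Simulated EFR level functions, on/off-CF scopes, scenarios |
| `R/stats-repro.R` | Permutation test, FDR, Bland–Altman, ICC, Shepherd's pi |
| `R/synthetic-data.R` | Seeded EEG/DPOAE/test-retest generators with ground truth |
| `R/interface.R` | Configuration, JSON round-trip, provenance, pipeline glue |
| `inst/cli/` | Command-line front ends for analysis and simulation |

See the methods vignette (`vignettes/methods.Rmd`) for the model equations,
parameter choices, and generator calibration.
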