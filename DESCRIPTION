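Package: efrcomp
Title: Cochlear Compression Estimates from Envelope Following Responses and Swept-Tone DPOAEs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating peripheral auditory compression from
    envelope-following-response (EFR) magnitude-level functions recorded with
    multi-frequency SAM-tone stimuli, and from swept-primary distortion-product
    otoacoustic emissions (DPOAEs). Implements the full EFR analysis chain
    (zero-phase band-pass filtering, artifact rejection, trial formation,
    inverse-variance weighted averaging, spectral readout with an F-test
    significance criterion and phase-to-latency conversion), constrained
    two-segment piecewise fitting of magnitude-level functions, a windowed
    least-squares swept-tone DPOAE analyzer with phase-inversion noise
    estimation and stopping rules, repeatability statistics (Bland-Altman,
    one-way ICC, permutation tests, Shepherd's pi), seeded synthetic-data
    generators with known ground truth, and an expected-rate phenomenological
    auditory-nerve population model used to decompose simulated EFRs into on-
    and off-characteristic-frequency contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: signal, jsonlite, stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
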