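Package: fpiapw
Title: Arterial Pulse Waveform Extraction from Fabry-Perot Interferometric Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demodulation pipeline for low-finesse Fabry-Perot interferometric
    recordings of arterial applanation tonometry. Converts raw interference
    intensity time series into arterial pulse waveform displacement curves via
    outlier repair, zero-phase Butterworth filtering, segment-wise min-max
    normalization, Hilbert-envelope feature detection, fringe-extremum and
    breakpoint annotation, halfwave counting, and cubic-spline displacement
    reconstruction. Includes a forward optical model that synthesizes
    interferograms from parametric pulse-waveform templates, and evaluation
    tools quantifying signal-to-noise ratio and feature-timing accuracy
    against simulated ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
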