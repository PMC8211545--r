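Package: circlux
Title: Single-Cell Circadian Oscillator Ensemble Analysis for
    Bioluminescence and Locomotor Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal single-cell bioluminescence
    recordings of circadian clock-protein reporters in cultured Drosophila
    brains, together with matched locomotor and sleep analysis of live
    flies. Builds programmable light schedules (standard LD, strobed LD,
    skeleton photoperiods, constant light or darkness, and weekend-style
    3-h phase delay/advance shifts), simulates ensembles of damped
    phase-amplitude oscillators with subgroup-specific light input and
    network coupling, processes raw frame stacks (cosmic-ray rejection,
    45-min binning, running-minimum denoising, ROI extraction with
    per-frame background subtraction), quantifies per-cell rhythmicity via
    translation-invariant wavelet detrending and sliding-window sine fits,
    estimates phases by time-delay embedding, measures ensemble synchrony
    with a waveform-based order parameter and randomization confidence
    bands, and scores fly sleep from beam-crossing counts with chi-square
    periodogram rhythmicity classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
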