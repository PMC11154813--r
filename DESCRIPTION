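Package: effortlab
Title: Listening-Effort Measurement from EEG Alpha Power and Pupillometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for physiological measurement of listening effort under
    degraded speech. Synthesizes noise-vocoded sentence-in-babble trials,
    simulates adaptive matrix-test staircases that estimate 50% and 80%
    speech reception thresholds against a virtual listener, computes
    trial-wise EEG alpha-band (8-12 Hz) power change between a
    baseline-in-noise window and a sentence-encoding window, preprocesses
    pupil traces (deblinking, interpolation, baseline correction,
    downsampling) to obtain maximum-pupil-dilation percent change, and
    provides the group statistics (Levene-gated independent t tests,
    Pearson correlation, noncentral-t power analysis) used to compare
    tinnitus and control cohorts. A synthetic-cohort generator with known
    ground truth supports end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    signal,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
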