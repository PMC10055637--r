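Package: leapd
Title: Linear Predictive Coding Evidence Accumulation for EEG-Based
    Cognitive Indexing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes a bounded EEG-based cognitive index from
    resting-state multichannel recordings.  Band-limited channels are
    encoded with linear predictive coding (LPC) via the Levinson-Durbin
    recursion, per-class affine subspaces are fitted in coefficient
    space for cognitively normal and cognitively impaired groups, and a
    test recording is scored by the relative distance to the two
    subspaces, fused across electrodes by geometric mean.  Includes the
    full training protocol (per-electrode band/order search, electrode
    selection), cross-validated evaluation (age-controlled Spearman
    partial correlation, ROC/AUC, classification metrics, linear vs
    quadratic regression, randomization tests, robustness sweeps),
    classical spectral baselines, and a seeded synthetic resting-state
    EEG cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
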