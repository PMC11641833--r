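Package: ppgci
Title: Cardiac Index State Classification from Finger Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for classifying low cardiac-index states (CI <= 2 L/min/m^2)
    from the finger photoplethysmogram (PPG). Implements the full analysis
    chain used in intraoperative hemodynamic monitoring research: a synthetic
    generator for paired PPG / continuous-thermodilution cardiac-index
    records, a plain-text record format with channel resampling, windowing
    and quality screening, per-window beat ensemble averaging with fiducial
    point detection (systolic peak, dicrotic notch, derivative landmarks),
    twenty published pulse-wave features, RReliefF predictor weighting for a
    continuous response, and gradient-boosted decision-tree classification
    with confusion-matrix evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
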