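Package: wristpa
Title: Raw Wrist Accelerometry Pipeline for Physical-Activity Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end processing of raw tri-axial wrist accelerometer
    recordings into minute-level physical-activity, jerk and entropy
    features and circadian average-day profiles, with the statistical
    layer used in late-life depression actigraphy studies: sphere-fit
    autocalibration to local gravity, cubic-spline resampling to 50 Hz,
    Butterworth band-pass gravity removal, 30-minute wear-time
    classification, day qualification, confound residualization,
    pooled-variance group tests, partial correlations with clinical
    outcomes, and control-referenced neuropsychological Z composites.
    Includes a synthetic cohort simulator with known ground truth
    (circadian intensity profiles, non-wear bouts, per-device
    miscalibration, planted group effects and outcome correlations) so
    every stage of the pipeline can be validated by recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
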