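Package: grpaca
Title: Gravity-Removal Physical Activity Classification and METs
    Calibration for Waist-Worn Triaxial Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes raw 32 Hz triaxial waist-accelerometer signals into
    10-second epoch features, removes the gravitational component with a
    second-order Butterworth high-pass filter (0.7 Hz cut-off), classifies
    epochs and activity bouts as locomotive or nonlocomotive from the ratio of
    unfiltered to filtered synthetic acceleration (GRPACA), and predicts
    metabolic equivalents (METs) with branch-specific linear equations
    calibrated for children. Includes indirect-calorimetry reference
    computations (Weir equation, RMR-relative METs), calibration machinery
    (stratified development/cross-validation splits, threshold sweeps, branch
    regression fits), agreement evaluation (per-activity difference tables and
    Bland-Altman limits of agreement), and a seeded synthetic-data generator
    for waveforms and full calibration cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
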