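Package: motorsig
Title: Motor-Signature Analysis of Tablet Gameplay Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for sensor-based digital phenotyping of young
    children's touch-screen gameplay. Reads session logs of raw touch events
    and 10 Hz inertial (accelerometer, gyroscope, attitude) streams, segments
    touch data into atomic gestures, extracts a 262-entry catalogue of
    kinematic and inertial features per child per game, classifies children
    into two groups (ASD-like vs control-like) by repeated stratified k-fold
    cross-validation with tree ensembles and pooled ROC analysis, and ranks
    discriminative features by the two-sample Kolmogorov-Smirnov distance.
    Includes a calibrated synthetic-cohort generator so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    rlang,
    yaml,
    stats,
    grDevices,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
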