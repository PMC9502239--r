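Package: pdwear
Title: Detecting Parkinson's Disease from Free-Living Wrist-Worn Inertial Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting Parkinson's disease (PD) from multi-day,
    unconstrained 6-channel wrist inertial recordings (triaxial accelerometer
    and gyroscope). Rules-based human activity recognition isolates 5-second
    "walk-like" events via per-subject adaptive amplitude thresholds and
    Welch power-spectral-density band dominance in the 0.6-2 Hz walking band;
    a one-dimensional convolutional neural network classifies each walk-like
    event as PD or healthy control, and per-day majority voting aggregates
    event predictions into a daily diagnosis. Includes hand-crafted spectral
    and moment features with four comparison classifiers, leave-one-subject-out
    cross-validation with temporal holdout evaluation, and a synthetic
    free-living cohort generator with tunable Parkinsonian gait effects
    (bradykinetic amplitude attenuation, 4-9 Hz tremor, cycle-time jitter)
    for fully reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    glmnet,
    randomForest,
    xgboost,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
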