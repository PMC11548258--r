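Package: gazefatigue
Title: Mental Fatigue Assessment from Eye-Movement Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assessment of operator mental fatigue from gaze recordings.
    Implements dispersion-based fixation and saccade detection as a function
    of the fixation-area diameter, per-sample gaze kinematics (velocity,
    acceleration, Menger curvature), a catalogue of 27 oculomotor
    characteristics, a four-criterion relevance-screening technique
    (Wilcoxon rank tests against a mental-performance split, inner-session
    dynamics, and maximal correlations with choice-reaction-time deltas and
    visual-analogue fatigue scores over a grid of fixation-area diameters),
    and a binary fatigue-classification pipeline with normalization,
    quasi-constant/Kendall/PCA feature selection, a classifier grid, and
    sliding-window assessment of streaming gaze data.  A seeded synthetic
    study simulator with controllable fatigue effects makes the whole
    pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    nnet,
    randomForest,
    rpart,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
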