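Package: errpfusion
Title: Hybrid EEG-Pupillometry Decoding of Error-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for multimodal decoding of
    error-related brain and autonomic responses in immersive
    human-computer interaction. Provides a synthetic-data generator for a
    virtual-reality flight paradigm (event schedules, 63-channel EEG with
    error-related potentials and ocular artifacts, gaze and pupil streams
    with foreshortening distortion and blinks, RR-interval series with
    respiratory sinus arrhythmia and post-error heart-rate deceleration),
    preprocessing chains for each modality (zero-phase Butterworth
    filtering, regression-based ocular artifact subtraction, blink
    interpolation, pupil foreshortening correction, artifact rejection,
    spherical-spline bad-channel interpolation), asynchronous
    sliding-window multiclass decoding with shrinkage linear discriminant
    analysis, hybrid EEG-pupil fusion by feature concatenation and by
    Bayesian confusion-matrix belief combination, and the accompanying
    significance statistics (cumulative-binomial chance thresholds,
    signed-rank and Friedman/Nemenyi group tests with FDR correction).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
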