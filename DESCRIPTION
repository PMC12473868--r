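Package: adlsteps
Title: Step Counting from Wearable Accelerometry During Activities of Daily Living
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to develop and evaluate step-counting algorithms for
    individuals with impaired, irregular gait using body-worn triaxial
    accelerometers during unscripted activities of daily living. Provides a
    seeded generator of annotated multi-sensor recordings with bout-structured
    walking, shuffling and non-step movement; orientation-invariant axis
    assignment, zero-phase Butterworth filtering and overlapping-window
    labelling; per-window time/frequency/correlation features; five step-count
    regressors scored under leave-one-subject-out cross-validation; a gamma
    log-link generalized linear model to compare sensing and analysis
    configurations; threshold-crossing and Morlet-wavelet baseline counters;
    and agreement statistics (MAPE, Friedman test, exact sign-rank bounds).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    xgboost,
    randomForest,
    e1071,
    nnet,
    caret,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
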