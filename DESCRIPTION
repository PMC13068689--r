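Package: pshhrv
Title: Heart Rate Variability Analysis and Prediction of Paroxysmal
    Sympathetic Hyperactivity Episodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize and predict paroxysmal sympathetic
    hyperactivity (PSH) episodes from single-lead ECG or beat-annotated
    RR-interval series. Implements Pan-Tompkins QRS detection with
    artifact correction, cubic-spline tachogram resampling, quadratic
    detrending, Welch band-power estimation in the VLF/LF/HF bands,
    multiscale sample entropy with short- and long-scale complexity
    indices, Morlet continuous-wavelet band-power time courses with
    linear trend regression, episode windowing with group statistics
    and PSH-AM scoring, and an RBF-kernel support vector machine
    classifier with random-forest feature selection, grid search,
    stratified tenfold cross-validation, and leave-one-feature-out
    ablation. A synthetic episode generator provides labeled cohorts
    with controllable autonomic structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
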