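Package: mindstate
Title: Driver Mental-State Classification from Multichannel EEG via
    Triclass Common Spatial Patterns and Histogram Gradient Boosting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for classifying driver mental states
    (drowsy / awake / neutral) from multichannel EEG. Continuous
    recordings are band-pass filtered and segmented into fixed-length
    epochs; a triclass extension of the common spatial pattern (CSP)
    algorithm -- simultaneous diagonalization of whitened class
    covariances, with the fatigue and neutral projections summed --
    reduces each epoch to per-component variance features; and a
    from-scratch multiclass gradient-boosted decision tree classifier
    with histogram-based split finding and depth-limited leafwise growth
    predicts the state. Includes a synthetic multi-subject EEG generator
    with class-specific spatial covariance structure, and intra-subject,
    inter-subject and leave-subjects-out transfer evaluation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr,
    xgboost,
    yaml
Config/testthat/edition: 3
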