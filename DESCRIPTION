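Package: connectopipe
Title: Functional Connectome Group Comparison, Behavioral Prediction and
    Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for resting-state functional connectomes:
    construction of Fisher-z connectivity matrices from region-of-interest
    time series (detrending, bandpass filtering, nuisance regression),
    Network-Based Statistics group comparison with permutation family-wise
    error control over connected-component size, Connectome-based
    Predictive Modeling of behavioral scores with cross-validation and
    permutation significance testing, and single-mediator bootstrap
    mediation linking hematological metrics to cognition through network
    connectivity. Includes a synthetic-cohort generator with planted
    ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
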