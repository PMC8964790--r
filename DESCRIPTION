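Package: fatiguenet
Title: Frequency-Banded Functional Connectivity Networks for Mental
    Fatigue Analysis of fNIRS Hemoglobin Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for mental-fatigue assessment from
    multichannel functional near-infrared spectroscopy (fNIRS) hemoglobin
    time series. Decomposes oxy-, deoxy- and total-hemoglobin signals into
    five physiological frequency bands with a zero-phase Chebyshev band-pass
    filter, fuses channels into regions of interest by entropy weighting,
    builds Pearson functional-connectivity networks, and characterises them
    with weighted clustering coefficient, characteristic path length and
    small-worldness against matched random-network nulls (with
    sparsity-thresholded unweighted variants). Includes fatigue-level
    labelling from MFI-20 questionnaire and n-back behavioural scores
    (k-means split plus a threshold scan), two-way ANOVA with Tukey-Kramer
    post-hoc comparisons, a 2,250-dimensional feature assembly, and
    random-forest fatigue-state classification with Gini-importance feature
    selection and genetic-algorithm hyperparameter tuning. A synthetic-data
    generator emulating band-limited inter-regional coupling makes the full
    pipeline testable without recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph,
    randomForest,
    e1071,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
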