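Package: dynconn
Title: Dynamic Functional Connectivity States and Topological Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity analysis for
    multivariate (ICA-derived) brain time series: tapered-window sparse
    inverse-covariance (graphical lasso) connectivity estimation, recurring
    connectivity-state identification by L1 k-means with elbow model
    selection, state temporal metrics (fractional window, mean dwell time,
    number of transitions), per-window graph-efficiency metrics aggregated
    over sparsity thresholds, and covariate-adjusted association testing of
    the resulting dynamics against a subject-level covariate such as body
    mass index, with false-discovery-rate control. Includes a
    Markov-switching covariance simulator that generates synthetic cohorts
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    signal,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
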