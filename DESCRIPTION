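Package: mdstates
Title: Latent Brain-State Dynamics of the Multiple-Demand System from ROI fMRI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits variational-Bayes Gaussian-emission hidden Markov models with
    automatic-relevance-determination state pruning to multi-subject, multi-ROI
    fMRI time series; matches latent brain states across independent cognitive
    tasks by state-space closeness (inverse Kullback-Leibler divergence) and
    state temporal closeness (correlation of transferred posterior time
    courses) with permutation significance; quantifies state dynamics
    (occupancy rates, empirical transitions) and per-ROI contributions via
    leave-one-ROI-out virtual lesions; relates state occupancy to behavioral
    cognitive-control indices (including race-model SSRT) through predictive
    canonical correlation analysis and univariate correlation. Includes a
    synthetic multi-task cohort generator with a planted shared state so the
    full pipeline is testable without restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
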