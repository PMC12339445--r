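Package: dmfconn
Title: Whole-Brain Dynamic Mean-Field Modelling of Static and Dynamic
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates regional brain activity with the reduced Wong-Wang
    excitatory/inhibitory mean-field model coupled through a structural
    connectome, converts synaptic activity to BOLD signals with the
    Balloon-Windkessel hemodynamic model, and fits simulations to empirical
    static and dynamic functional connectivity (FC variance, temporal
    correlation, node cohesion) by grid search. Includes association
    statistics with permutation nulls and FDR control, ridge-regression
    prediction with nested cross-validation and permutation feature
    importance, region-wise coupling perturbation with spin-test map
    correlations, and a synthetic-data generator providing ground-truth
    cohorts for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
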