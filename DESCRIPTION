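Package: tcdcm
Title: Dynamic Causal Modeling of a Thalamo-Cortical Attention Network
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and inversion of bilinear dynamic causal models (DCM)
    for a six-region thalamo-cortical sustained-attention network. Enumerates a
    162-model hypothesis space over permuted fronto-thalamic connections,
    integrates the bilinear neural state equation through a balloon-Windkessel
    hemodynamic observation model, estimates subject-level posteriors and free
    energy by variational Laplace, performs random-effects Bayesian model
    selection (expected and exceedance probabilities), averages parameters over
    models in Occam's window by Bayesian model averaging, and runs one-sample
    and independent-samples t-tests on the averaged connectivity parameters.
    Includes a synthetic-cohort generator emulating a blocked continuous
    performance task (CPT-IP) with two attention-demand conditions and two
    groups, so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
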