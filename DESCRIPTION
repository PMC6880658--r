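Package: lldnet
Title: Symptom Network Analysis of Late-Life Depression with Comorbid Anxiety
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimation and comparison of regularized partial-correlation
    networks over ordinal psychiatric symptom ratings, built around the
    MADRS/BAI instruments used in geriatric depression research. Provides
    two-step maximum-likelihood polychoric and polyserial correlation,
    graphical-lasso precision estimation with EBIC penalty selection,
    weighted node centrality, nonparametric bootstrap stability diagnostics,
    a permutation network comparison test for global strength, global
    structure and individual edges, propensity-score matching (logistic
    model, 1:1 greedy nearest neighbour with caliper) to separate symptom
    severity from network structure, and a latent-Gaussian threshold
    simulator with known sparse partial-correlation truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
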