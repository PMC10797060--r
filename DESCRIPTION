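Package: mminet
Title: Network Analysis of Multimorbidity Indices in Spinal Cord Injury Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating pairwise Markov random field networks
    (Gaussian graphical, Ising, and mixed graphical models) over binary
    secondary health conditions and continuous health-status scores in
    spinal-cord-injury survey cohorts, with EBIC model selection, centrality
    and bootstrap stability analysis, a network-driven reduction of the
    30-item Multimorbidity Index to a short form, and regression-based
    comparison of the full and reduced indices. Includes a synthetic-cohort
    generator with planted network structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
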