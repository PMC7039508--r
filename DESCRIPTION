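Package: phylodwell
Title: Phylogenetic Comparative Analysis of Dwelling Size and Post-Marital Residence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cross-cultural phylogenetic comparative analysis of average
    house floor area (AHFA) and post-marital residence (PMR) in
    pre-industrial societies. Recodes Ethnographic-Atlas-style categorical
    variables to analysis traits, measures phylogenetic signal (Pagel's
    lambda for continuous traits, Fritz and Purvis's D for binary traits),
    fits phylogenetic generalized least squares regressions with residual
    lambda estimated by maximum likelihood, reconstructs ancestral states
    under Brownian motion, and tests for correlated evolution of two binary
    traits with Pagel's (1994) four-state Markov models. Includes a
    synthetic-data generator emulating the structure of such studies with
    known ground truth, and an end-to-end pipeline producing signal,
    model-comparison, ancestral-state and coevolution tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
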