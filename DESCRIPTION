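Package: pgtrait
Title: Gene-Content Prediction and Evolutionary History of Peptidoglycan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting peptidoglycan (PG) metabolic capacity from
    genome gene-family content and for tracing the evolutionary history of
    the underlying genes.  Implements a minimal 3-gene-set classifier over
    CAZy glycosyltransferase/glycoside-hydrolase family counts with
    diagnostic-value evaluation against three-valued literature truth,
    association statistics (chi-squared, phi correlation, PCA, logistic
    regression of PG absence on genome covariates), gain-penalizing
    asymmetric-cost parsimony reconstruction of gene gain/loss events on a
    phylogeny, Pagel-style correlated-evolution testing with a Monte-Carlo
    error percentage, clustering of co-occurring gain/loss events, and
    synthetic-data generators (Yule trees, correlated binary character
    histories, annotation cohorts) so every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
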