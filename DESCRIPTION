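Package: funcpheno
Title: Data-Driven Functional Phenotypes and Their Biopsychosocial Correlates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Defines functional phenotypes in schizophrenia-spectrum disorders
    by bootstrapped Ward clustering of functioning items with index-vote
    selection of the number of clusters and Promax-rotated principal
    components, then identifies key biopsychosocial correlates of the
    phenotypes with budgeted exhaustive subset searches over linear
    discriminant models (backward elimination and forward selection with a
    consistency fixing rule), validated by one-vs-rest L1-regularized
    regression and fused into a final consensus discriminant model. Includes
    a synthetic-cohort generator with planted cluster, loading and predictor
    structure so the whole pipeline can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    glmnet,
    cluster,
    jsonlite,
    generics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
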