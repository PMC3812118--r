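Package: grnvar
Title: Quantitative Genetics of Expression Variation in a Developmental
    Gene Regulatory Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing naturally occurring variation in gene
    expression across a developmental gene regulatory network measured in a
    North Carolina II (NCII) breeding design. Estimates dam, sire,
    dam-by-sire and residual variance components per gene and time point
    with a Gibbs-sampled Bayesian hierarchical mixed model (with a
    method-of-moments cross-check), compares correlation structure between
    known regulator-target pairs and non-interacting genes via
    topology-aware permutation tests, classifies regulatory edges as
    sensitive or insensitive to upstream variation, relates expression to
    skeletal morphology through PCA, maternal-conditioned linear models and
    two-block partial least squares with the RV coefficient, and ships a
    seeded synthetic-data generator that emulates the cross, network and
    morphology structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
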