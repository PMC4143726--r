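Package: famscan
Title: Multiphase Linkage and Family-Based Association Analysis of
    Quantitative Traits in Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a multiphase genetic analysis of a quantitative
    trait measured in extended pedigrees: censoring-aware phenotype
    adjustment by censored normal regression with pedigree random
    intercepts (antihypertensive medication treated as right-censoring
    of underlying blood pressure), two-point variance-components
    linkage analysis with exact or Monte-Carlo single-marker
    identity-by-descent estimation and LOD-based region selection, and
    family-based association in selected regions by the measured
    genotype test and the quantitative transmission disequilibrium
    test, optionally with a marker-specific linkage variance component.
    Includes a gene-dropping simulator of pedigrees, genotypes and
    longitudinal phenotypes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    lme4,
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
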