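Package: crossgs
Title: Genomic Selection of Purebreds for Crossbred Performance with Dominance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation and analysis of two-way crossbreeding
    programs under genomic selection with a dominance trait architecture.
    Simulates a historical population, breed formation and expansion on a
    one-Morgan chromosome; samples additive and dominance QTL effects and
    scales them to target variance components; estimates additive and
    dominance SNP effects from purebred training data with a Bayesian LASSO
    Gibbs sampler; computes true and genomic breeding values for purebred and
    crossbred performance and their additive/dominance partitions; runs
    truncation-selection scenarios contrasting selection criteria and
    reference-population structures; and summarises linkage-disequilibrium
    decay and between-breed persistence of LD phase.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    vcfR,
    optparse
Config/testthat/edition: 3
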