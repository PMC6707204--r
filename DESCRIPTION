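Package: triodnm
Title: Statistical Analysis of De Novo and Rare Inherited Variation in Trio Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable toolkit for the statistical machinery of family-based
    exome studies of neurodevelopmental disorders. Implements de novo burden
    testing against a calibrated per-gene mutation-rate model with exact
    one-sided Poisson tests, transmission-disequilibrium analysis of rare
    founder singletons with variant-quality (VQSLOD) threshold calibration,
    detection of postzygotic mosaic mutations by a filter/binomial-deviation
    branch and an empirical-Bayes beta-binomial EM mixture, de novo TADA
    gene discovery with Gamma relative-risk priors and Bayesian FDR,
    covariate-matched resampling tests for laminar and cell-type expression
    enrichment, hypergeometric network over-connectivity tests, consensus
    merging of CNV calls by reciprocal overlap, and chromosome aneuploidy
    screening from depth and heterozygosity summaries. A synthetic trio-cohort
    generator with known ground truth drives testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
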