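Package: twtest
Title: Three-Way Test for Multi-Trait Multi-Variant Association from GWAS
    Summary Statistics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-based association testing of multiple traits against
    multiple genetic variants using only GWAS summary Wald statistics and a
    reference genotype panel. Implements covariate-aware estimation of the
    Kronecker-structured null correlation of the Z-score matrix (trait
    correlation from null-SNP Z-scores, SNP partial correlation from a
    reference panel after projecting out stratification axes), three
    complementary quadratic-form statistics combined by the Cauchy
    combination test, and parametric-bootstrap calibration of truncated
    quadratic forms by three-cumulant generalized chi-square matching.
    Includes summary-statistics input/output with allele harmonization and
    gene windowing, and a simulation engine for type-I-error and power
    studies under configurable signal allocations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
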