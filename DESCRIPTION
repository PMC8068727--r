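Package: latentpgs
Title: Latent Polygenic Scores and the Meta-Structure of Psychopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolchain for studying the phenotypic and polygenic
    meta-structure of correlated traits in population samples: genotype quality
    control and two-stage ancestry principal-component selection, polygenic
    score construction from GWAS summary statistics (no LD trimming, no p-value
    threshold), confirmatory factor analysis with robust corrections, fit
    indices and the four-level measurement-invariance ladder, LD-score
    regression, genetic-covariance factor models fitted by diagonally weighted
    least squares with block-jackknife sampling covariances, per-SNP latent
    factor weights for latent polygenic scores, and association models with
    ancestry covariates. A synthetic-data module generates genotypes with block
    LD, multi-trait GWAS summary statistics under a latent genetic factor model
    with controllable sample overlap, and phenotype panels under common-factor
    models with group shifts, so the whole chain is testable with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
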