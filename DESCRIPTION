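Package: h2part
Title: Genome-Partitioned Heritability and Genetic Correlation via Multi-GRM REML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for partitioning the genetic variance and covariance of
    quantitative traits across subsets of sequence variants. Builds additive
    genomic relationship matrices (GRMs) from PLINK-format genotypes, defines
    variant subsets from functional annotation and from windowed
    linkage-disequilibrium (LD) score, variant density and allele-frequency
    quartiles, and fits univariate and bivariate mixed models with one or two
    GRMs by average-information restricted maximum likelihood (AI-REML).
    Derived statistics include subset and chip heritabilities, genetic
    correlations, relative covariances, per-variant summaries, and six
    subset-level LD characterization parameters. A block-mosaic genotype and
    phenotype simulator provides known-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
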