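Package: pubgrowth
Title: Admixture-Aware GWAS of Pubertal Growth Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for genome-wide association
    studies of pubertal growth in admixed cohorts. Provides a seeded
    simulator of admixed cohorts (Balding-Nichols reference panels,
    Dirichlet global ancestry, Markov local-ancestry tracts, genotypes and
    longitudinal heights), a shape-invariant growth model fitted by
    alternating penalized least squares that derives peak height velocity
    (PV), age at peak height velocity (APV) and height at APV (HAPV),
    genotype and sample quality control (exact Hardy-Weinberg test,
    missingness, heterozygosity, method-of-moments IBD relatedness
    pruning), supervised maximum-likelihood estimation of global ancestry
    proportions, and per-SNP linear models with sex and local-ancestry
    interaction terms tested by Wald contrasts, plus global-ancestry
    effect regressions and significance classification.
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
    readr,
    rlang,
    stats,
    splines,
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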