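Package: troutgp
Title: Single-Step Genomic Evaluation, GWAS and Genomic Prediction for
    Growth Under Thermal Stress in Rainbow Trout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic evaluation of growth traits in aquaculture
    breeding nuclei, built around the single-step GBLUP framework. The
    package simulates pedigreed fish populations with gene-drop genotypes
    and polygenic traits, applies marker and sample quality control (minor
    allele frequency, call rate, exact Hardy-Weinberg test), constructs
    pedigree (A), genomic (VanRaden G) and combined single-step (H inverse)
    relationship matrices, estimates variance components and heritability
    by average-information REML, performs weighted single-step GBLUP GWAS
    with per-SNP variance decomposition and lead-SNP gene-window lookup,
    evaluates genomic prediction accuracy under repeated cross-validation
    with GWAS-based marker preselection and LD pruning, and benchmarks
    genotype imputation accuracy with a masking design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
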