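Package: snptrait
Title: Candidate-Gene SNP Diversity, Trait Association and Relative Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for candidate-gene SNP studies in livestock and
    poultry cohorts. Computes per-locus marker diversity statistics (allele and
    genotype frequencies, expected heterozygosity, polymorphism information
    content, effective allele number, Hardy-Weinberg chi-square tests), fits
    unbalanced two-factor fixed-effects models of quantitative traits on
    genotype and sex with pairwise genotype comparisons rendered as dual-alpha
    compact letter displays, and quantifies relative gene expression from qPCR
    Ct values by the 2^-ddCt method with Student's t-tests. Includes a seeded
    synthetic-cohort generator (genotypes with controllable Hardy-Weinberg
    departure, additive-model traits, Ct tables) so every stage is testable
    with known ground truth.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    car,
    emmeans,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
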