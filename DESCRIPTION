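Package: adipotwin
Title: Twin-Cohort Smoking Methylation and Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for studying smoking-associated DNA
    methylation and gene expression in twin cohorts: linear mixed-model
    epigenome-wide and transcriptome-wide association contrasting current
    and never smokers with family and zygosity random effects,
    methylation-expression integration via covariate-adjusted Spearman
    correlation, a nonparametric smoking-cessation reversal statistic,
    repeated split-sample smoking-status prediction, cis-meQTL mapping on
    covariate-adjusted residuals, and adiposity-phenotype main and
    interaction models including prediction of future visceral-fat change
    after cessation. Includes a fully parameterised synthetic twin-cohort
    generator (methylation beta values, expression, genotypes with explicit
    parental transmission, and longitudinal adiposity phenotypes) so the
    whole pipeline is testable without any external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    generics,
    ggplot2,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
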