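Package: amdgrs
Title: Genetic Risk Score Modelling for Late-Stage Age-Related Macular
    Degeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates a weighted genetic risk score (GRS) for
    late-stage age-related macular degeneration from case-control
    genotype-dosage data. Provides per-SNP case-control association
    statistics (additive logistic odds ratios, Hardy-Weinberg exact tests,
    single-SNP AUC), joint multi-SNP logistic risk models, equal-width
    five-category risk classification with exact conditional odds ratios,
    prevalence-reweighted absolute-risk projection for a modelled general
    population, screening metrics, repeated random-subsampling
    cross-validation, backward parsimonious model search, and a calibrated
    synthetic case-control cohort generator for testing the full pipeline
    without individual-level data.
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
    tibble,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
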