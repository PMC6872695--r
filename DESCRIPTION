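Package: hetpet
Title: Radiogenomic Analysis of Tumor Genetic and Metabolic Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for joint analysis of tumor genetic heterogeneity and
    FDG PET metabolic heterogeneity in head and neck squamous cell
    carcinoma. Computes the mutant-allele tumor heterogeneity (MATH)
    score from MAF-style variant tables, extracts six metabolic features
    (SUVmax, SUVpeak, MTV, TLG, histogram entropy, coefficient of
    variation) from segmented SUV volumes after trilinear resampling,
    associates the genomic and imaging domains by Spearman rank
    correlation, and stratifies overall survival with maximally selected
    log-rank cutoffs, combined two-feature risk groups, and Cox
    proportional-hazards models. Includes a seeded synthetic-cohort
    generator (subclonal VAF mixtures, heterogeneous tumor phantoms,
    proportional-hazards outcomes) so the full pipeline is testable
    without external data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
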