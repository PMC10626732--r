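Package: chemomethyl
Title: Detection and Decay of Treatment-Associated DNA Methylation Changes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for epigenome-wide analysis of
    treatment-associated DNA methylation: quality control and
    beta-mixture quantile (BMIQ) normalization of beta-value matrices,
    reference-based cell-type deconvolution by robust partial
    correlations with LUMP immune-content scoring, paired and
    single-time-point differential methylation with empirical-Bayes
    variance moderation and Bonferroni calling, promoter-level
    aggregation, pre-ranked gene-set enrichment with both gene-resampling
    and outcome-label permutation nulls, and estimation of effect-size
    attenuation with time since treatment. Ships a synthetic-cohort
    generator with planted ground truth so every stage is testable
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
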