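Package: metscore
Title: Continuous Metabolic-Syndrome Score Construction and Candidate-SNP
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a continuous metabolic-syndrome (MetS) severity score
    from six quantitative risk factors (waist circumference, diastolic and
    systolic blood pressure, glucose, HDL cholesterol, triglycerides) by
    principal component analysis with varimax rotation, after normality
    screening and trait-specific normalizing transforms.  Provides the
    harmonized dichotomous MetS classification with medication overrides,
    Hardy-Weinberg equilibrium testing, dominance-model two-sample
    association of candidate SNPs with the score (from raw data or published
    summary statistics), Bonferroni correction, trend tests over genetic
    risk counts, covariate-adjusted linear-model estimates with an
    incremental R-squared screening rule, minimum-detectable-difference
    power analysis, and a synthetic-cohort generator with the latent
    two-factor structure the score model assumes, so every stage is testable
    without access to individual-level survey data.
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
    vcfR
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
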