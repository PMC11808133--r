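Package: exposcan
Title: Exposure-Wide Survival Scans, Composite Risk Scores, and
    Attributable-Fraction Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for exposure-wide risk-factor analysis
    of incident disease in biobank-style cohorts, built around Parkinson's
    disease as the motivating outcome. Provides a synthetic cohort
    generator with known ground truth; baseline-variable preprocessing
    (special-code recoding, mode/median imputation, instance averaging,
    dummy coding, exclusion rules); Cox proportional-hazards fitting with
    Schoenfeld-residual diagnostics and a time-interaction fallback; a
    Bonferroni-corrected exposure-wide association scan with collinearity
    filtering and subgroup replication; polygenic risk scores; two-sample
    Mendelian randomization estimators (inverse-variance weighted,
    weighted median, MR-Egger) with heterogeneity diagnostics; composite
    weighted domain risk scores and gene-environment joint models;
    difference-method mediation with bootstrap inference; and
    population-attributable-fraction estimation under Levin's formula with
    PCA-communality weighting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
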