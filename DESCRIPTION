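Package: glycotwin
Title: Glucose Tracking and Twin-Based Heritability Analysis for
    Longitudinal OGTT Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal glycemic analysis in same-sex twin
    cohorts: derivation of HOMA-IR and ADA glycemic status from oral
    glucose tolerance test measurements, age- and sex-specific tertile
    tracking with transition matrices and prediabetes incidence,
    twin-pair-clustered regression via generalized estimating equations
    with exchangeable working correlation, and maximum-likelihood ACE
    variance-component decomposition for continuous traits and for binary
    traits under a liability-threshold model with tetrachoric
    correlations and profile-likelihood confidence intervals. Includes a
    synthetic twin-cohort generator with known genetic architecture and
    longitudinal tracking so every analysis stage is testable without
    access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
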