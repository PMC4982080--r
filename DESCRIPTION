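Package: longimeta
Title: Longitudinal Meta-Analysis of Child PTSD Prevalence and Symptom Course
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Random-effects meta-analysis of the course of posttraumatic
    stress disorder (PTSD) in trauma-exposed children and adolescents over
    the first year after trauma. Builds study-level effect sizes from
    longitudinal cohort data: logit-transformed point prevalence, relative
    prevalence reduction between assessment waves (with attrition
    imputation and sensitivity variants), and standardized mean symptom
    change with a pre-post correlation-indexed variance. Pools them with
    the DerSimonian-Laird estimator (Q, tau-squared, I-squared), fits
    univariable random-effects meta-regressions with REML and
    Knapp-Hartung inference over prespecified moderators, and provides
    funnel-plot diagnostics. Includes a child-level multi-study simulator
    with known truth for parameter-recovery and coverage experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
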