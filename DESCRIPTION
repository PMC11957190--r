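Package: mirmod
Title: Screening miRNA Modifiers of the Social Adversity-Traumatic Stress
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical framework for identifying micro-RNAs that modify
    the association between social adversity and post-traumatic stress
    symptom severity (PTSS) in longitudinal cohort data. Provides
    outcome-distribution selection by maximum likelihood and BIC with a
    bootstrap family comparison, a from-scratch negative-binomial GLM
    engine (IRLS with profile-likelihood dispersion, Wald and
    likelihood-ratio tests, optional L1 penalty), genome-wide main-effect
    and adversity-by-miRNA interaction screens with modulation scores and
    Benjamini-Hochberg FDR gating, 10-fold cross-validated Spearman model
    comparison, a cross-wave rank-sum consistency test, hypergeometric
    pathway enrichment over score-filtered miRNA target genes, and a
    synthetic cohort generator with planted effects so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    fitdistrplus
Config/testthat/edition: 3
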