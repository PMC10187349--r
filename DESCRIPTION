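Package: tgfbsig
Title: Derivation and Evaluation of a Prostate Cancer-Specific TGF-beta
    Activity Signature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving a prostate cancer-specific TGF-beta activity
    gene signature from a six-condition epithelial/stromal co-culture
    contrast, scoring samples with a tau-weighted single-sample gene set
    enrichment (ssGSEA) running sum, selecting signature size by local-maximum
    AUC, testing gene-wise differential expression with empirical-Bayes
    variance moderation and patient-blocked random-intercept mixed models,
    counting PTEN/TP53 altered alleles for a 3-allele radiotherapy-outcome
    classifier, and calling biochemical recurrence from PSA series by the
    Phoenix nadir+2 rule. Includes synthetic-cohort generators that emulate
    the repeated-biopsy study structure so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
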