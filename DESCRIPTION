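Package: pathprs
Title: Pathway-Specific Polygenic Risk Scores for Blood Pressure Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates pathway-restricted polygenic risk scores
    (PRS) for systolic and diastolic blood pressure and their derived traits
    (mean arterial pressure, pulse pressure) using the clumping-and-
    thresholding method across three non-overlapping cohorts: a discovery
    cohort for per-SNP association testing, a validation cohort serving as
    LD reference and for p-value threshold selection, and a target cohort
    for evaluation.  Pairwise linkage disequilibrium is estimated from
    unphased genotypes by maximum-likelihood (EM) haplotype frequencies.
    Evaluation covers incremental R-squared over covariate-only models,
    PRS-decile contrasts (pooled t, Cohen's d), hypertension discrimination
    (AUC with DeLong confidence intervals) and pathway-PRS correlation
    structure.  Includes a seeded synthetic-cohort generator with LD-blocked
    genotypes, pathway-concentrated heritability, covariate and
    population-structure effects, and antihypertensive-medication use, so
    the full pipeline is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    fgsea,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
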