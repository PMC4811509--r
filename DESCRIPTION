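Package: methsig
Title: Prognostic DNA-Methylation Signature Selection for Neuroblastoma-Style Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating prognostic DNA-methylation
    marker signatures from methylation-specific PCR (MSP) call matrices and
    MBD-seq style region count data. Implements pi-score ranking of
    differentially methylated regions with input-background exclusion,
    ternary MSP methylation calling against a positive control with ACTB
    sample quality control, per-sample methylation scores, and a robust
    three-step signature-selection framework (metric x assay-cutoff x
    score-cutoff grid search, bootstrap Jaccard stability, weighted harmonic
    mean selection). Includes Kaplan-Meier / log-rank survival validation,
    logistic regression and Fisher exact association reporting, a Freedman
    log-rank power calculation, and a seeded synthetic-cohort generator so
    the whole pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
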