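Package: dnmeth
Title: Leukocyte Methylation Analysis of Diabetic Nephropathy Risk
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Region-level differential methylation analysis for
    methyl-capture sequencing count data with genomic, CpG-context and
    transcription-factor-binding-site annotation, together with a clinical
    arm that builds a core-gene methylation index, assigns KDIGO renal risk
    categories, classifies longitudinal eGFR decline, evaluates prediction
    improvement by bootstrap delta-AUC, and pools cohort-level evidence by
    weighted median-difference meta-analysis with Fisher's combined
    probability test. Includes synthetic-data generators with known ground
    truth so the whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
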