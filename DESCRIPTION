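Package: cnvpopscan
Title: Population-Scale CNV Discovery and Summaries from SNP-Array Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for population-scale copy-number variant (CNV)
    screening from SNP genotyping array signals (Log R Ratio and B allele
    frequency). Provides cohort simulation with realistic probe spacing and
    copy-number class structure, per-sample signal quality control with
    GC-wave correction, a distance-aware hidden Markov model caller with
    per-call Bayes factors run under two parameterizations, dual-track
    consensus merging with Bayes-factor thresholding calibrated against
    qPCR delta-delta-Ct copy numbers, CNV-region construction and
    classification, permutation tests for colocalization with segmental
    duplications, gene annotation, and per-breed population summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
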