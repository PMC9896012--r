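Package: crossbind
Title: Cross-Factor Chromatin Binding Interaction Analysis for bHLH-PAS
    Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dissecting competitive and cooperative
    chromatin-binding interactions between transcription factors that share
    a limiting dimerization partner, as in the HIF/AHR/ARNT system. Provides
    dual-caller consensus peak calling with an empirical background filter,
    canonical-site definition and Venn classification, normalised
    differential binding with negative-binomial Wald tests, summit-distance
    statistics, NCGTG motif-variant enrichment, pre-ranked weighted gene-set
    enrichment, and metagene composite scoring of paired tumour cohorts.
    Includes a synthetic-data generator built on a competitive-dimerization
    occupancy model so the whole pipeline can be exercised end-to-end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
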