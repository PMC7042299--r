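Package: famprio
Title: Germline Variant Prioritization in Familial MDS/AML
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for prioritizing candidate germline predisposition
    variants in families with myelodysplastic syndrome (MDS) and acute
    myeloid leukemia (AML). Provides pedigree and phenotype handling with
    cohort summaries, annotated variant loading with allele-frequency,
    depth and segmental-duplication pre-filtering, pedigree segregation
    assessment tolerant of reduced penetrance, triage of variants in
    established predisposition loci against per-gene inheritance models,
    a whole-exome discovery cascade with gene-level cross-family
    recurrence aggregation and external candidate-list rescue,
    constitutional deletion interval analysis, qPCR telomere length
    (T/S ratio) flagging against healthy-control centiles, and a
    synthetic familial cohort simulator for end-to-end validation and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
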