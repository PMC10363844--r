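Package: pedcns
Title: Consensus Somatic Calling and Molecular Subtyping for Pediatric CNS
    Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A downstream somatic-analysis toolkit for pediatric central
    nervous system tumor cohorts. Builds consensus single-nucleotide and
    copy-number variant calls from multiple callers, rescues hotspot
    mutations, resolves copy-number events at arm, cytoband and gene level,
    computes tumor mutation burden and hypermutation classes, scores
    pairwise mutation co-occurrence, filters and prioritizes gene fusions,
    collapses expression matrices to unique gene symbols, and assigns
    research-grade molecular subtypes with WHO-2016-aligned rule lists,
    including TP53 status integration. Ships a seeded synthetic-cohort
    generator emulating multi-caller outputs with known truth so every
    stage is testable without controlled-access data.
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
    stringr,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
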