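Package: chromaccess
Title: Pan-Cancer Chromatin Accessibility Analysis from ATAC-seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for clinical analysis of ATAC-seq chromatin
    accessibility in cancer cohorts: curation of a fixed-width pan-cancer
    peak set from per-sample summit calls (summit extension, iterative
    overlap removal, score normalization, quality filters), normalization of
    the peak-by-sample count matrix (prior count, CPM, log2, quantile
    normalization, replicate averaging), a permutation-based chromosomal
    accessibility landscape, promoter-peak association with clinical groups
    (Mann-Whitney with Benjamini-Hochberg correction), and per-peak survival
    analysis (Cox proportional hazards and Kaplan-Meier median splits).
    Includes a synthetic-cohort generator with planted effects so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    limma,
    stats,
    survival,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
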