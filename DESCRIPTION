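Package: exomir
Title: Exosomal Small RNA Cargo-Sorting Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested, reusable pipeline for comparing small-RNA cargo of
    exosomes against their parent cells, modelled on KRAS-isogenic colorectal
    cancer lines. Covers adapter trimming and length filtering, exact and
    mismatch-tolerant alignment with multi-mapper weighting, hierarchical
    ncRNA annotation with extended mature-miRNA windows, isomiR 3' trimming,
    tailing and non-templated-addition classification by iterative
    trim-and-remap, negative-binomial differential enrichment with TMM
    normalization and seven-way set partitioning, Spearman/PCA sample
    summaries, delta-delta-Ct and standard-curve qPCR arithmetic, reporter
    normalization, and deterministic export-motif scanning. A synthetic-data
    generator with per-read ground truth makes every stage testable without
    sequencing downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
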