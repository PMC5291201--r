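Package: rvmqtl
Title: Region-Collapsed Rare-Variant Methylation QTL Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps methylation quantitative trait loci (mQTL) driven by sets of
    low-frequency and rare variants collapsed over CpG-island-anchored regions
    (islands, shores, shelves). Implements a weighted variance-component kernel
    association test for quantitative traits from first principles, including
    Beta(MAF) variant weights, the mixture-of-chi-square null distribution with
    an exact quadratic-form tail and a moment-matched fallback, and a
    permutation oracle. Provides cis/trans scan orchestration, single-variant
    follow-up, conditional analysis on known index SNPs with D-prime based
    pruning, leave-one-out stability diagnostics, and a coupled synthetic-data
    generator with ground-truth effect records for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    BiocGenerics,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
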