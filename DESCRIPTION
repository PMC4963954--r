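Package: epigsc
Title: Integrative Epigenomic Analysis of Germline Stem Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative epigenomic analysis of germline stem
    cells: classification of active and poised enhancers from H3K4me1 and
    H3K27ac ChIP-seq peaks, bivalent promoter detection from H3K4me3 and
    H3K27me3, K-means clustering of binned ChIP-seq signal around peak
    centers, window-based DNA methylation quantification for capture
    (MethylCap/MeDIP) and bisulfite assays, exact-binomial methylation
    calling with FDR control, cross-platform methylation comparison, and
    expression statistics linking chromatin state to transcription. A
    seeded synthetic-data generator with planted ground truth makes the
    whole pipeline testable end to end.
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
    tools,
    utils,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
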