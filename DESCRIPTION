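Package: deltadnase
Title: Differential DNase-Seq Accessibility and Nuclear Receptor Footprint
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of chromatin accessibility changes upon
    nuclear receptor activation from per-base DNase I cleavage profiles.
    Calls DNase I hypersensitive (DHS) peaks with a gamma-tail threshold on
    kernel-smoothed cut density, detects differential accessibility over
    adaptively tiled 300-bp windows with a negative-binomial exact test at
    strict (FDR) and loose (raw p) thresholds, associates differential
    regions with differentially expressed genes by permutation, scans
    sequence with a first-order log-likelihood position weight matrix
    scanner, and clusters base-pair-resolution footprint profiles with a
    cross-run k-means stability statistic. A synthetic-data module
    generates replicate cut profiles, sequence, gene models and expression
    counts with planted accessibility changes and footprints so the whole
    pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
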