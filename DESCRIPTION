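Package: unmetr
Title: Per-Base Difficulty-to-Sequence Scores for Protein-Coding Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives per-nucleotide difficulty-to-sequence (UNMET) scores for
    protein-coding positions from a flag-annotated population variant catalog.
    Windowed variant density and variant filter rate statistics label reliable
    and unreliable variant-call sites; ten per-base genomic features (coverage
    depth z-value, (K,E)-mappability, homopolymer, tandem-repeat, interspersed
    repeat, segmental-duplication, low-complexity, structural-variant masks,
    GC content and sequence entropy) feed a gradient-boosted tree classifier;
    raw predictions are converted to percentile-rank scores with difficulty
    banding and browser-track export. Includes a deterministic synthetic-data
    generator so the full pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    vcfR,
    xgboost
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
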