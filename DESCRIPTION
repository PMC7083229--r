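Package: ribostall
Title: RNA Surveillance Factor Binding and Ribosome Stall-Site Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing protein-RNA crosslinking (CRAC/CLIP) and
    ribosome profiling data with a focus on translation surveillance:
    read-level filtering and UMI deduplication, detection of non-templated
    homopolymeric 3' tails, per-transcript binding profiles and metagene
    plots, relative-binding normalization across decay factors,
    hexamer/frame-resolved stall-site scoring from RNA-fragment 3' ends,
    monosome and disome A-site assignment, ERCC-anchored mRNA half-life
    estimation, RNA structure/sequence motif enrichment with resampled
    backgrounds, negative-binomial tests for rRNA binding sites,
    strand-specific genomic window classification, and uORF annotation and
    quantification. A synthetic-data generator provides ground-truth
    transcriptomes, reads, alignments and count tables for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    Biostrings,
    Rsamtools,
    edgeR,
    DESeq2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
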