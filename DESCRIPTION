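Package: grnrewire
Title: Transcription-Factor Network Rewiring from Paired RNA and ATAC Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying condition-dependent rewiring of
    transcription-factor (TF) regulatory programs from paired bulk RNA-seq and
    ATAC-seq, with ChIP peak-set integration. Implements negative-binomial
    differential testing with a cell-line blocking factor and median-of-ratios
    normalization, position-weight-matrix scanning of peak sequences with
    min-max match scoring, positional motif density and peak-set motif
    enrichment, motif-family clustering by position-frequency-matrix
    similarity, Tn5 insertion-profile footprinting with permutation-based
    differential binding calls, condition-specific gene-regulatory-network
    construction with degree-centrality differencing, and two-factor cistrome
    stratification with genomic-context annotation. A fully seeded synthetic
    multi-omic generator (toy genomes, planted motifs, negative-binomial count
    matrices, Tn5 fragment files, ground-truth networks) supports end-to-end
    recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
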