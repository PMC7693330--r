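Package: sglscan
Title: Discovery and Comparative Genomics of Single-Gene Lysis ORFs in
    ssRNA Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens positive-sense single-stranded RNA phage (levivirus)
    genomes for candidate single-gene lysis (sgl) open reading frames
    embedded in alternate reading frames of the core genes, using three
    criteria: minimum length, an upstream Shine-Dalgarno motif, and a
    hydrophobic (transmembrane-like) stretch scored by Kyte-Doolittle
    hydropathy. Assigns each candidate to one of 18 genomic-context
    regions relative to the mat-coat-rep gene architecture, computes the
    MILC codon-usage statistic, performs affine-gap pairwise alignment,
    dot plots, substitution/indel divergence censuses and mutation
    nomenclature, builds neighbor-joining trees with bootstrap supports
    and clade extraction, and ships a synthetic-genome generator that
    plants dual-frame lysis ORFs and decoys with an exact ground-truth
    ledger so that every stage is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
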