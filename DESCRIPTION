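Package: mirusmine
Title: Recovery and Intron Landscape Analysis of Mirusvirus Genomes from
    Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision layer for recovering mirusvirus (phylum Mirusviricota)
    genomes from metagenomic bins and for characterizing their spliceosomal
    intron landscape. Provides rule-based contig taxonomy, iterative
    metagenome-assembled genome (MAG) construction with rescue of highly
    divergent genomes, single-copy core-gene completeness and redundancy
    scoring, ANI-based dereplication, arbitration between intron-aware and
    intronless gene predictions, intron extraction and splice-class
    assignment, introner and intron-nested gene detection, trans-splicing
    detection from junction evidence, and multi-rooted relative
    evolutionary divergence (RED) rank delineation. A synthetic-community
    generator with full truth tables makes every step testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    phytools,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
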