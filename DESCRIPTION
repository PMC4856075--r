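Package: srnakit
Title: Small RNA Sequencing Simulation, Classification and Differential
    Expression for C. elegans-Style Libraries
Version: 0.1.0
Authors@R:
    person("srnakit", "developers", email = "srnakit@example.org",
           role = c("aut", "cre"))
Description: Tools for the analysis of bulk small RNA sequencing libraries of
    the kind produced from C. elegans: 3' adapter trimming and barcode
    demultiplexing, collapsing of identical reads, best-stratum ungapped
    alignment with at most three mismatches, a length-dependent mismatch
    filter, classification of reads into miRNA (via a 5'-end window around
    annotated mature 5' ends), piRNA, structural RNA, transposon and
    endogenous siRNA categories with Argonaute-pathway partitioning
    (CSR-1, WAGO, ALG-3/4, ERGO-1), and count-based differential expression
    using TMM normalization, a quantile-adjusted conditional maximum
    likelihood common dispersion and the negative binomial exact test with
    Benjamini-Hochberg FDR control. A fully deterministic synthetic-data
    generator builds toy annotated genomes and barcoded, adapter-ligated
    read libraries with per-read ground truth so that every pipeline stage
    can be validated without external data. Also provides the chi-square
    penetrance test and Welch t test used for scoring genetic-interaction
    phenotypes (adult alae, ASE neuron marker, seam cell counts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
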