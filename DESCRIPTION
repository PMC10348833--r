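Package: SpliceFrags
Title: Novel Splice Junction Guessing, Transcript Fragment Indexing and
    Signature-Based Read Counting
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies potentially novel alternative splicing
    from short RNA-seq reads without a genomic spliced alignment. Genes are
    partitioned into subexons (the smallest exonic units bounded by splice
    sites or transcript ends), novel junctions are guessed by recombining
    annotated donor and acceptor sites, and a minimal set of transcript
    fragments is built so that every read of a given length maps within one
    fragment. A light-weight k-mer pseudoalignment engine assigns each read
    a mapping signature (the increasing sequence of subexon indices it
    overlaps); signature counts can be converted to transcript
    compatibility counts, per-subexon counts, merged counting bins and
    splicing-graph node/edge counts, and every novel intron is classified
    into alternative-splicing event types. Novel splice sites reported by
    an external spliced aligner can be incorporated in a refinement phase.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: AlternativeSplicing, RNASeq, Transcriptomics, Alignment,
    Software
RoxygenNote: 7.3.3
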