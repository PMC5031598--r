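Package: GCxMotif
Title: Codon-Position GC Content and DSB Hotspot Motif Enrichment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes genic and codon-position GC content (GC1, GC2, GC3)
    from a genome and its GFF3 annotation with full CDS phase handling,
    classifies genes into high/low GCx classes at an inclusive 80% cutoff,
    scans sequences for a degenerate GC-rich 3-nt-periodic double-strand-break
    hotspot motif with a position weight matrix at a fractional-score
    stringency, maps motif instances into codon frames, summarises motif GC
    periodicity with variance-gated t tests, and quantifies enrichment of
    motif-containing genes in high-GCx and meiotic-expression classes with
    genome-proportion goodness-of-fit chi-square tests. Includes a synthetic
    genome simulator (FASTA + GFF3 + truth tables) so every pipeline stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: Genetics, SequenceMatching, MotifDiscovery, Coverage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
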