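Package: pingphase
Title: Small RNA Locus Discovery, piRNA/siRNA Biogenesis Signatures, and
    RNAi Trigger Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates small-RNA-producing loci from genome-aligned small RNA
    reads and characterizes their biogenesis with the three pairwise signature
    statistics used in insect RNAi work: ping-pong 10-nt 5' overlaps, phased
    trailing-1U distances, and Dicer 2-nt 3'-overhang duplex geometry, each
    summarized as a Z-score over an offset spectrum. Loci are triaged by
    short/long read-size ratio, strand bias and expression, then placed into
    five categories (siRNA, cis-NAT, no-bias, piRNA, piRNA cluster); individual
    reads are labeled as ping-pong piRNA, phased piRNA or siRNA. A phased-strand
    selection rule drives the design of piRNA-trigger fusion constructs that
    embed a gene-of-interest between flanks of an endogenous piRNA locus. A
    seeded simulator plants each biogenesis signature in a synthetic genome and
    emits a truth manifest so the whole pipeline is testable without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
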