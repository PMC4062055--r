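Package: triodmr
Title: Species-Specific Differentially Methylated Region Discovery by
    Three-Species Triangulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative MeDIP-seq methylome analysis across a three-species
    trio (a reference species plus two out-groups). Calls methylation
    enrichment peaks with two independent callers, triangulates consensus
    peaks across species through chain-based liftover with a minMatch
    threshold and a reciprocal back-lift filter, and classifies
    reference-species hypo- and hypermethylated species-specific
    differentially methylated regions (s-DMRs). Downstream analyses cover
    CpG-island/shore enrichment with fractional-overlap counting and shuffle
    controls, biophysical position-weight-matrix occupancy divergence between
    species, and gene-body methylation differential ranking. A deterministic
    synthetic trio-genome generator with planted methylation truth, exact
    chain files and MeDIP-like fragment simulation makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
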