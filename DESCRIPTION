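Package: circscreen
Title: Transcriptome-Wide Screening of Circular RNA and RNA-Binding Protein Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening interactions between circular RNAs (circRNAs)
    and RNA-binding proteins (RBPs) from backsplice-junction call tables and
    eCLIP binding-site data. Builds a consensus circRNA catalog from two
    independent callers, categorizes exons relative to backsplice junctions,
    computes merged RBP binding-site coverage of circularizing and
    non-circularizing exons with expression-matched resampling and empirical
    p-values, tests enrichment of RBP binding sites and inverted Alu pairs in
    introns flanking circRNAs, quantifies knockdown effects on circRNA
    expression in reads per million, maps short eCLIP reads across candidate
    backsplice junctions with PCR deduplication, and summarizes Gene Ontology
    enrichment and subcellular co-localization of predicted interactions. A
    synthetic-data generator emulates every input format with planted effects
    so the full screen runs end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
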