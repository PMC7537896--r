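Package: mybkit
Title: Annotation Toolkit for Plant MYB Transcription Factor Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide surveys of the plant MYB transcription
    factor family, modelled on the R2R3-MYB catalog of banana (Musa
    acuminata DH-Pahang). Detects tandem MYB repeats in protein sequences
    with a position-weighted local aligner and classifies domain
    architectures (1R, R2R3, 3R, 4R); scans for the bHLH-interaction
    consensus motif; builds neighbor-joining trees with bootstrap support
    from extracted MYB domains and assigns query proteins to labelled
    reference clades, flagging lineage-specific groups; computes
    gene-structure and chromosomal-distribution statistics from GFF3 gene
    models; normalises RNA-Seq counts to FPKM and classifies per-gene
    expression breadth across organ groups. A synthetic-data generator
    with a planted-truth manifest makes every stage testable without
    external downloads, and the published 294-gene banana MYB catalog and
    its 17-sample expression table ship as plain-text fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    phangorn,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
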