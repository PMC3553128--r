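Package: mircascade
Title: Small RNA-Seq miRNA Quantification, Cascade Mapping and Differential
    Expression with qPCR Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for mature microRNA
    quantification from short-read small RNA sequencing data, built around
    a sequential mapping cascade (miRNA hairpins, then other non-coding
    RNA, genome and contaminant decoys, then a relaxed hairpin remap) with
    explicit mature-assignment rules (full-length ungapped placement with
    at most one mismatch, a minimum 7-nt overlap with an annotated mature
    arm, and discard of reads overlapping multiple matures). Downstream
    stages implement median-of-ratios size-factor normalization, a
    conditional negative-binomial exact test with Benjamini-Hochberg false
    discovery control, delta-delta-Ct relative quantification of qRT-PCR
    plates with direction-concordance reporting against the sequencing
    results, consensus miRNA target selection across prediction programs
    with shared-target clustering and hypergeometric pathway
    over-representation, and tissue/cell-line expression concordance.
    Synthetic-data generators with full ground truth make every stage
    exercisable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
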