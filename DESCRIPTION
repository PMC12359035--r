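Package: smsites
Title: Transcriptome-Wide Discovery of Sm-Sites and Sm-RIP Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate Sm-protein binding sites (Sm-sites) in
    transcript sequences by scanning for the uridine-rich U1-, U2-, U5-,
    U7-type and degenerate noncanonical motifs, capturing flanking sequence
    windows, and requiring predicted RNA secondary structure on both flanks
    via a weighted base-pair-maximization folder. Builds transcript models
    from GFF3/GTF annotation, assigns sites to mRNA regions (5'UTR, CDS,
    3'UTR), scans for 5' splice-site and branch-point mimics, constructs
    intron intervals and counts intronic reads, and stratifies RIP-seq
    log2 fold-changes by Sm-site class with one-sided Wilcoxon rank-sum
    tests and Benjamini-Hochberg correction. Includes a synthetic
    transcriptome and count simulator with planted ground truth so every
    stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
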