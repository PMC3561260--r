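Package: mecp2screen
Title: Integrated Window-Level ChIP-Seq and Expression Screen for MeCP2
    Target Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated screen for MeCP2 target genes in astrocytes.
    Quantifies diffuse, domain-level ChIP-seq binding as input-subtracted
    RPKM in three strand-aware windows per gene (around the transcription
    start site, over the gene body, and around the transcription end site),
    calls the top decile of genes per window, runs a stringent microarray
    differential-expression screen (detection-call prefilter, unpaired t
    test with raw-P or Benjamini-Hochberg modes, fold-change gate,
    probe-to-gene collapse), intersects the two to produce per-window
    target sets, and validates candidates with comparative-Ct (delta-delta
    Ct) qPCR arithmetic and standard-curve quantitation. A synthetic-data
    module generates annotation, reads, expression matrices and Ct tables
    with planted truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Rsamtools,
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
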