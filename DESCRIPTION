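Package: chondratac
Title: Consensus Open-Chromatin Analysis for Chondrocyte ATAC-Seq with
    GWAS Enrichment and TF Footprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis toolkit for bulk ATAC-seq of fetal bovine
    chondrocytes integrated with RNA-seq: Tn5 cut-site correction
    (+4/-5 bp), fragment-size periodicity and TSS-enrichment quality
    control, a sliding-window Poisson peak caller, replicate-consensus
    peak construction by reciprocal overlap, priority-ordered genomic
    feature annotation, hypergeometric over-representation tests,
    permutation-based GWAS-SNP enrichment in open chromatin, PWM motif
    scanning with aggregate footprint classification, and TPM-based
    expression filtering.  A synthetic-data module generates every
    input with known ground truth so the whole workflow is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
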