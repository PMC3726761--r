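Package: passengerScan
Title: Auditing Passenger-Region Confounding in Knockout Mouse Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for detecting strain-derived passenger regions that
    confound knockout-versus-wildtype comparisons in mouse functional
    genomics. Implements two-group differential expression on RNA-Seq counts
    with an exact negative-binomial test and Benjamini-Hochberg FDR control,
    directional gene-signature shift analysis by the sign test, windowed
    strain-informative SNP density scanning with contiguous region calling,
    positional enrichment of top differentially expressed genes in called
    regions (chi-square and Fisher exact tests), and element-wise
    capture-based methylation load comparison across TSS, exon, intron and
    intergenic elements. A synthetic-data module generates count matrices,
    annotations, variant tables and methylation profiles with recoverable
    ground truth, so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    withr
Config/testthat/edition: 3
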