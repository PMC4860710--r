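Package: methcap
Title: Differential Methylation and Expression Analysis for Methyl-Capture Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative methylome/transcriptome analysis workflow for
    methyl-capture (MeDIP-style) short-read sequencing of case/control
    designs. Calls differentially methylated regions from tag counts via
    sliding-window Poisson enrichment, TMM normalization and the
    negative-binomial exact test; profiles hyper- and hypomethylation across
    genomic feature classes as log2 odds ratios with Woolf confidence
    intervals and Fisher tests; computes direction-consistent region overlaps
    between disease models; and links methylation to expression through
    preranked gene set enrichment analysis with gene-set permutation FDR.
    Includes a seeded synthetic-data generator with planted ground truth for
    calibration and recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    edgeR,
    ape,
    jsonlite
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
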