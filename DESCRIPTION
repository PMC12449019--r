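Package: isomiRatlas
Title: miRNA-Space Construction, IsomiR Classification and
    Tissue-Specificity Statistics for Small RNA-Seq Atlases
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds exact-match miRNA-space references from genome and
    hairpin annotations, places and classifies small-RNA reads as canonical
    miRNAs or isomiR variants (5' and 3' templated shifts, non-templated 3'
    tails, mixed forms) with seed-shift detection and reads-per-million
    quantification. Implements an auditable sample- and feature-level
    quality-control filter cascade for multi-source expression atlases,
    consolidation and ortholog-based naming of predicted novel miRNA loci,
    robust rank aggregation of per-sample expression rankings via beta
    order statistics, and the organ-enrichment index for tissue
    specificity. Includes a synthetic-data generator producing genomes,
    annotations, labelled reads and expression matrices with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcriptomics, Sequencing, SmallRNA, GeneExpression,
    QualityControl
RoxygenNote: 7.3.3
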