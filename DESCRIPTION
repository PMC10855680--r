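Package: SRCRfam
Title: Annotation and Molecular-Evolution Analysis of the Scavenger Receptor
    Cysteine-Rich Gene Superfamily
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide analysis of the scavenger receptor
    cysteine-rich (SRCR) gene superfamily: integration of domain and
    homology evidence into a per-species inventory, tandem-duplication
    cluster calling by a gene-rank distance rule, conserved-cysteine motif
    classification of SRCR domains into Groups A, B and C, exon-intron
    architecture reconstruction with protein-to-genome domain projection,
    paralog exon similarity and exon-loss detection, duplication-unit
    typing, and tissue-expression summarization. Includes a synthetic
    genome-with-ground-truth generator so every analysis step is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'SRCRfam-package.R'
    'utils.R'
    'formats-io.R'
    'synthetic-data.R'
    'inventory.R'
    'tandem-clusters.R'
    'cysteine-motif.R'
    'gene-structure.R'
    'expression-profiles.R'
    'pipeline.R'
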