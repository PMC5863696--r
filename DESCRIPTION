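Package: synortho
Title: Collinearity-Guided Orthology Inference and Cross-Species
    Functional Annotation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for annotating protein-coding genes in a reference
    genome by comparative evidence from multiple related genomes. Extracts
    conserved multiple-alignment anchors (MAAs) from whole-genome multiple
    alignments, detects multi-level collinear segments from ordered genomic
    markers by anchor chaining, infers orthologous gene pairs scored with a
    composite support score (OPSS) combining collinearity degree and
    bidirectional best hits, transfers ontology terms across species through
    the inferred orthologs, and compares and validates annotation sets with
    Jaccard indices, Wang semantic similarity and a co-expression based
    Kolmogorov-Smirnov procedure. Ships a seeded generator of synthetic
    comparative-genomics worlds with planted collinear blocks, orthologs,
    ontology annotations and co-expressed modules for end-to-end testing.
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
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: ComparativeGenomics, Annotation, GenomeAnnotation, GO,
    Alignment, GeneExpression
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'coexpr.R'
    'collinearity.R'
    'formats-maf.R'
    'formats-obo.R'
    'formats-tables.R'
    'maa.R'
    'orthology.R'
    'pipeline.R'
    'semsim.R'
    'synortho-package.R'
    'synth.R'
    'transfer.R'
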