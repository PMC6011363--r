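Package: cisNATseq
Title: Cis-Natural Antisense Transcript Discovery, Alternative Splicing and
    Strand-Specific Differential Expression for Plant Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide discovery and classification of cis-natural
    antisense transcript (cis-NAT) pairs from full-length transcript models,
    with single-linkage clustering of overlapping transcripts into
    transcript units and classification of opposite-strand overlaps into
    head-to-head, tail-to-tail and fully overlapping geometries.  Companion
    tooling covers strand-specific fragment counting and FPKM normalisation,
    a pooled negative-binomial conditional exact test with
    Benjamini-Hochberg correction for differential expression of genes and
    NATs, enumeration and differential testing of the four classical
    alternative-splicing event types (intron retention, exon skipping,
    alternative acceptor, alternative donor), hypergeometric GO-term
    enrichment, leaf physiology formulas (Arnon chlorophyll content and
    gas-exchange net photosynthesis), and a seeded synthetic-data generator
    that emulates a two-condition, three-replicate, dUTP strand-specific
    study design with planted ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'as-events.R'
    'cisNATseq-package.R'
    'quantify.R'
    'diff-stats.R'
    'nat-discovery.R'
    'physiology.R'
    'synthetic-data.R'
    'pipeline.R'
    'transcript-model.R'
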