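Package: sjquant
Title: Splice-Junction-Based Quantification of Alternative Splice Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-centric quantification of alternative splice variants from
    spliced RNA-seq alignments. Derives the splice junctions that uniquely
    discriminate each transcript of a gene from its annotation, counts
    junction-spanning reads in SAM/BAM files under stringent anchor and
    mapping filters, and expresses variants as Splice Junction Tags Per
    Million (SJ TPM) together with gene-relative isoform fractions, replicate
    averaging and group summaries. Includes projection of the canonical
    protein domain architecture through each variant, validation of
    junction-spanning qPCR primers with in-silico PCR, and a seeded
    spliced-read simulator that provides ground truth for every pipeline
    stage.
License: MIT
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
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    data.table,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
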