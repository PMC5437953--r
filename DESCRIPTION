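Package: methylomap
Title: Downstream Analysis of Whole-Genome Bisulfite Sequencing Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitation and comparative analysis of CpG methylation from
    whole-genome bisulfite sequencing call tables: global and per-site
    methylation summaries with symmetric-CG pooling, bisulfite
    conversion-efficiency estimation, genome-wide running-window and
    transcription-start-site quantitation, gene-body methylation,
    size-standardised trend profiles over genes and transposable elements,
    expression-quintile stratification of promoter methylation from RNA-seq
    counts, and bootstrap calibration of the margin of error of global
    methylation at low sequencing depth. Includes a seeded synthetic
    methylome generator emulating vertebrate (pervasively methylated) and
    invertebrate mosaic methylome architectures so that every stage can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
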