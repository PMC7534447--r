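Package: waspkit
Title: Genome Curation, CpG Methylation Signatures and Pan-Genome
    Analysis for Social-Wasp Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for chromosome-level insect genome projects:
    assembly summary statistics (N50, N content, gap runs, soft-masked
    repeat fraction), rule-based contig decontamination using BLAST
    taxonomy keywords, orthogroup rescue and a GC-content band, chromosome
    and scaffold renaming by size rank, per-gene CpG observed/expected
    ratios with BIC-selected Gaussian mixture components as a DNA
    methylation signature, orthogroup sharing and pan/core-genome
    rarefaction, and ultrametric tree age scaling. Includes seeded
    synthetic-data generators so every stage can be validated without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    ape,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
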