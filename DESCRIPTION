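Package: oripool
Title: Deconvolution and Analysis of Barcoded Plasmid Origin Pools
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for discovering functional plasmid origins of replication
    with DNA-barcoded combinatorial ("magic pool") plasmid libraries. Models
    golden-gate style four-part assemblies and assembles full plasmid records
    in silico; deconvolutes long reads of the pooled library into a
    barcode-to-parts association table under read-support and conflict rules;
    turns per-sample barcode counts (BarSeq) into per-origin enrichment
    fractions, barcode-diversity tallies and functional/carryover/artifact
    origin calls; and estimates relative plasmid copy number per genome from
    colony qPCR data with per-well amplification-efficiency correction.
    Includes a ground-truthed synthetic-data generator so every stage can be
    exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
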