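Package: trxscreen
Title: Analysis of Dual-Luciferase RNAi Screens for Trithorax-Group Regulators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the complete downstream analysis of kinome-wide
    dual-reporter (Firefly/Renilla luciferase) RNAi screens for regulators of
    trithorax-group dependent gene activation. Implements plate-median
    normalization, relative reporter activity, dual-channel artifact masking,
    robust Z-score hit calling with control-derived cut-offs, secondary-screen
    validation by Welch t-tests, delta-delta-Ct relative expression analysis,
    ChIP peak annotation relative to transcription start sites with gene-set
    overlap counts, and ordinal phenotype scoring for genetic-interaction
    crosses. A synthetic-data module generates every input the pipeline
    consumes with known ground truth, so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
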