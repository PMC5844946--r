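Package: braintrx
Title: Small-RNA Quantification, Count-Based Differential Expression,
    RNA-Editing Indices and Delta-Delta-Ct Analysis for Brain
    Transcriptome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of the bespoke computational
    stages used in bulk transcriptome studies of neurodegenerative
    disease brain tissue: exact-overlap assignment of small-RNA reads to
    mature miRNAs with adapter trimming and expression filtering; a
    count-based differential-expression procedure built on upper-quartile
    normalization, log2 fold changes and Welch t-tests with
    Benjamini-Hochberg correction; A-to-I RNA-editing levels, the Alu and
    recoding editing indices, site filtering and per-site differential
    editing; and delta-delta-Ct relative quantification from RT-qPCR Ct
    tables with geNorm- and NormFinder-style reference-gene stability
    selection. Every pipeline input can be simulated with known ground
    truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
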