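Package: engramtx
Title: Engram Transcriptomic Signatures from Single-Cell and Spatial Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying long-term fear-memory engram signatures in
    activity-labelled (TRAP/tdTomato) single-cell RNA-seq and targeted spatial
    transcriptomics data. Implements quality control and log-normalization for
    gene-by-cell count tables, Mann-Whitney-Wilcoxon differential expression, a
    triple-criteria remote-memory DEG screen over TRAPed cells, one-vs-all
    marker selection for MERFISH gene panels, 30-micrometre peri-engram spatial
    neighborhood analysis, neuropeptide-ratio statistics, a cross-region shared
    DEG co-direction analysis, and seeded synthetic-data generators that plant
    recoverable engram, salience, background-activation and residual-training
    gene classes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
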