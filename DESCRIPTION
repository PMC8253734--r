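Package: prismscreen
Title: Pooled Barcoded Cell-Line Screens: Simulation, Barcode Counting and Scoring
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for multiplexed (PRISM-style) pooled cell-line screens in
    which each cell line carries a unique 26-bp DNA barcode. Provides a
    generative simulator of pool growth under compound or CRISPR perturbation
    and of two-step PCR amplicon sequencing reads; mismatch-tolerant barcode
    extraction and counting from FASTQ; spike-in-referenced and
    control-anchored normalization of barcode abundances, including
    viability adjustment of the spike-in reference; per-line dose-response
    AUC and sgRNA-averaged CRISPR dependency scoring; and quality-control
    utilities (Cas9 efficiency gating, dilution-series linearity, replicate
    concordance).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Software, Sequencing, CRISPR, PooledScreens, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
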