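Package: chromDA
Title: Differential Activity of Chromatin Domains from Gene Expression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects chromatin domains (TADs or compartment domains) whose
    member genes change expression in a coordinated way between two sample
    conditions. Implements a fold-change concordance (FCC) score with a
    genome-wide AUC-ratio test against an expression-stratified
    gene-to-domain permutation null, and a per-domain significance caller
    that combines the mean log2 fold-change (mFC, permutation null) and the
    mean intra-domain expression correlation (mCor, cross-boundary null)
    with Stouffer's method and Benjamini-Hochberg correction. Includes the
    companion procedures (artificial cross-boundary partitions, shared
    boundary ratio, immune-domain flagging via tumor purity, gene-family
    co-domain networks, conserved differentially active regions, and a
    differential interactome test on precomputed contact significance), a
    synthetic data generator with planted ground truth, and a command-line
    interface.
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
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    limma,
    yaml
biocViews: GeneExpression, DifferentialExpression, HiC, Epigenetics,
    Transcriptomics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
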