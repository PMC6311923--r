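Package: DHScan
Title: Variable-Length DNase I Hypersensitive Site Classification with a
    Gated-Inception Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies DNase I hypersensitive sites (DHSs) from DNA sequence
    alone using a gated-inception convolutional neural network whose spatial
    pyramid pooling (SPP) head accepts fragments of any length between 200 and
    800 bp. Provides the full supporting pipeline: corpus construction from a
    genome (FASTA) and DHS intervals (BED) with length-matched negative
    sampling and greedy redundancy removal, length-binned multi-scale training
    with on-chromosome fragment extension, evaluation statistics (sensitivity,
    specificity, accuracy, Matthews correlation coefficient, ROC/AUC), and a
    synthetic planted-motif fixture generator so the whole pipeline is
    exercisable without external downloads. The network (gated convolutions,
    inception blocks, 1-D SPP, batch normalisation, SGD with momentum) is
    implemented in base R matrix algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
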