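Package: epistate
Title: Chromatin-State Segmentation and Regulatory-Genome Annotation for
    Single-Cell Histone-Modification Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for annotating the regulatory genome of multi-cell-type
    epigenomes from binarized chromatin tracks. Implements a multivariate
    Bernoulli-emission hidden Markov model (ChromHMM-style) with maximum
    likelihood fitting, Viterbi segmentation and emission re-estimation;
    a two-criterion procedure for choosing the number of chromatin states
    and consolidating a learned model into eight descriptive states;
    cross-cell-type state statistics (coverage, conservation, variation,
    transitions, methylation by state); candidate cis-regulatory element
    annotation, differential-region testing and enhancer-validation
    metrics; and single-cell quality-control procedures (species-mixing
    doublet-rate estimation, rate-matched doublet removal, feature-count
    filters, gene-activity scores, clustering-agreement metrics). A
    synthetic-epigenome generator with known ground truth supports
    end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
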