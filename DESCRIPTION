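Package: lifecna
Title: Untargeted ctDNA Detection from Low-Coverage Plasma cfDNA Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects circulating tumor DNA (ctDNA) in plasma cell-free DNA
    (cfDNA) from low-coverage (~6x) whole-genome sequencing without prior
    knowledge of tumor mutations. Implements global fragment-length profiling
    and short-fragment enrichment calls, regional short/long (S/L) fragment
    ratio analysis in 100 kb bins z-scored against a healthy control panel,
    coverage-dip analysis over transcriptionally active chromatin region sets,
    genome-wide and focal somatic copy number alteration (SCNA) calling on
    short (90-150 bp) fragments via circular binary segmentation with
    chromosome-specific limit-of-blank thresholds, and a stacked machine
    learning ensemble (support vector machine, random forest, neural network,
    elastic net, with a logistic meta-learner). Includes a synthetic cfDNA
    cohort generator (control panels, tumor profiles, in silico dilution
    series) so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    jsonlite,
    e1071,
    ranger,
    nnet,
    glmnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
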