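Package: crosspath
Title: Cross-Tissue Trait-Pathway Network Construction from Multi-Tissue
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores pathway activity per tissue and animal with the
    topology-weighted Pathway Connectivity Index (PCI), builds a
    permutation-thresholded pathway co-expression network gated by curated
    pathway-pathway links, identifies trait-relevant and trait-linking
    pathways across tissues, and refines and topologically analyzes the
    merged trait-pathway network (degree distributions, Brandes betweenness,
    MCODE-style dense subregions, Fisher enrichment with BH FDR).  Includes
    a synthetic multi-tissue cohort generator with planted co-active
    pathway groups and trait effects for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    Rcpp,
    fgsea,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
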