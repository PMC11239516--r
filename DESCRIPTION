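Package: replifork
Title: Single-Cell DNA Replication Fork Profiling and Speed Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of single-cell EdU pulse-labeling
    sequencing (scEdU-seq) molecule tables: per-cell quality control,
    S-phase ordering of cells from pairwise overlap of kernel-smoothed
    replication profiles, hidden semi-Markov segmentation of reads into
    replication fork tracks, pair-correlation analysis of within-cell
    read distances with a four-component mixture model to estimate
    per-cell DNA replication fork speeds from double-pulse labeling,
    simulation-based correction of Poisson sampling bias, and
    annotation-conditioned speed comparisons (replication timing scores,
    initiation-zone correlation, expression-overlap weighting).  Includes
    seeded simulators of pulse-labeled replication tracks and whole-cell
    read patterns so the entire pipeline can be exercised without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    uwot,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
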