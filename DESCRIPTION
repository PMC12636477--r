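Package: fiberburst
Title: Single-Molecule Chromatin Fiber Footprinting and Transcription-State Analysis
Version: 0.1.0
Authors@R:
    person("Fiberburst", "Developers", email = "fiberburst@example.org",
           role = c("aut", "cre"))
Description: Decodes per-molecule adenine-methylation footprinting data
    (Fiber-seq style) into protein footprints with a two-state
    sequence-context-conditioned hidden Markov model, classifies footprints
    into nucleosome, RNA polymerase II, pre-initiation complex and
    transcription-factor occupancy, detects Pol II convoys and
    hyperburst/active/refractory fiber states, discovers candidate
    cis-regulatory elements from aggregate accessibility, models per-fiber
    transcription states from element accessibility with L1-penalized
    logistic regression including dropout delta-AUC and subset synergy
    statistics, orders accessibility combinations into regulatory
    trajectories, and scans elements for footprint-supported
    transcription-factor motifs. A synthetic fiber generator with planted
    ground truth makes every stage verifiable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    glmnet,
    jsonlite,
    Biostrings,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
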