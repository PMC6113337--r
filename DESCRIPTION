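Package: netphase
Title: Core Community Recovery and Phase-Transition Detection in Temporal Networks
Version: 0.1.0
Authors@R: person("netphase", "developers", role = c("aut", "cre"),
    email = "netphase@example.org")
Description: Recovers the core community structure of a sequence of weighted
    network snapshots and detects the epochs at which that structure changes.
    Each snapshot adjacency matrix is decomposed into a low-rank community
    component plus sparse and dense noise via an alternating splitting
    augmented Lagrangian method (a three-block ADMM for robust PCA with dense
    noise).  Phase-transition epochs are located by scanning the thresholded
    rank of window-averaged low-rank components with recursive zoom-in, and
    per-segment communities are extracted by spectral clustering of
    segment-averaged low-rank matrices.  Includes seeded generators for
    factor-model, stochastic block model and weighted stochastic block model
    temporal networks with planted community timelines, a Kuramoto coupled
    oscillator simulator emitting phase-similarity networks, evaluation
    metrics (modularity, relative polarization, node variation,
    misclassification against planted truth), Matrix Market / edge-list IO
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
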