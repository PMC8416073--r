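Package: gcasym
Title: Multiscale Germinal-Center Simulation with Asymmetric Division of
    Antigen and Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation of the germinal-center (GC) reaction in
    which every B cell carries a bistable BLIMP1/BCL6/IRF4 gene-regulatory
    network integrated as ordinary differential equations. Centroblasts divide
    in the dark zone under somatic hypermutation, centrocytes compete for
    follicular-dendritic-cell antigen and T-follicular-helper help in the
    light zone, and selected cells recycle, differentiate into plasma cells or
    memory B cells, or return for further rounds of selection. Division of
    internalized antigen and of the three transcription factors is
    parameterized by per-species asymmetry probabilities and polarity levels,
    enabling scenario sweeps over coupled and uncoupled asymmetric-division
    regimes, with DZ-to-LZ ratio dynamics, output-cell kinetics and the
    temporal memory-to-plasma-cell switch as the primary observables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
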