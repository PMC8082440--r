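Package: wishplan
Title: Prioritized Multi-Criteria Fluence Optimization and Beam-Angle
    Selection for Mediastinal Radiotherapy Planning Studies
Version: 0.1.0
Authors@R: person("wishplan", "developers", role = c("aut", "cre"),
    email = "wishplan@example.org")
Description: A desk-scale implementation of an automated radiotherapy
    planning pipeline for mediastinal lymphoma: synthetic female-thorax
    phantom generation, coplanar and non-coplanar candidate beam geometry
    on the gantry-couch sphere, an analytic pencil-beam dose-influence
    engine, lexicographic ("wish-list") epsilon-constraint fluence
    optimization, greedy integrated beam-angle optimization, exact
    dose-volume-histogram plan metrics with clinical goal checking, and a
    population comparison protocol (24 beam configurations per patient,
    Wilcoxon signed-rank statistics, beam-direction histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    quadprog,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    rhdf5,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
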