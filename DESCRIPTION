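Package: dcrws
Title: Switching State-Space Models for Argos Animal Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian two-state switching first-difference
    correlated random walk (DCRWS) state-space models for error-prone,
    irregularly timed Argos satellite telemetry. Provides reading, speed
    filtering and gap segmentation of raw Argos location data; joint MCMC
    estimation of regular-step locations and discrete behavioral states
    across individuals sharing movement parameters, with a t-distributed
    observation model indexed by Argos location class; classification of
    posterior behavioral modes into transit and area-restricted search with
    per-state movement descriptors; extraction and day/night summarization
    of dives from archival-tag depth series; and a synthetic-data generator
    producing ground-truthed two-state tracks and diel-structured dive bouts
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    geosphere,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
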