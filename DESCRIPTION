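Package: gaitid
Title: Footwear-Aware Human Gait Identification from Ground Reaction
    Forces and Body Height
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage open-set identification of walking subjects from
    force-plate ground reaction force (GRF) recordings fused with
    depth-sensor body-height measurements.  Strides are compared with
    dynamic time warping over gait sub-phases (mid stance, terminal
    stance, full stride); the candidate gallery is first reduced by a
    body-height gate, with the measured height corrected for high-heeled
    footwear detected from loading-response GRF polynomial features.
    Decisions are made by a rank-weighted ensemble of five
    nearest-neighbour voters with a rejection threshold.  A seeded
    synthetic-gait generator (GRF morphology plus two-sensor skeleton
    streams) supports end-to-end evaluation of the pipeline under the
    five standard enrollment/probe footwear scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
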