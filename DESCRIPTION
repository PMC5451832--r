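Package: rodtrack
Title: Segmentation, Tracking and Genealogy of Rod-Shaped Bacteria in
    Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Maintainer", "rodtrack", email = "rodtrack@example.org",
           role = c("aut", "cre"))
Description: Joint segmentation and tracking of rod-shaped bacterial cells
    in 2-D time-lapse image stacks. Cell boundaries are extracted with
    distance-regularized level set evolution (DRLSE), cell divisions are
    detected from the intensity profile across the septum along each cell's
    major axis, and identities are propagated frame to frame by minimizing a
    global trajectory energy (constant-velocity, exclusion and
    regularization terms). The package reconstructs lineage trees, extracts
    single-cell growth statistics (size at birth and division, division
    time, elongation rate), evaluates results with Dice, segmentation
    outcome categories, MOTP and MOTA, and ships a synthetic colony
    simulator that renders growing, dividing capsule cells with exact
    ground-truth masks and lineage for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ape
Config/testthat/edition: 3
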