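Package: acroplan
Title: Screw Corridor Planning for Acromial Fracture Fixation from 3D Bone Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans two parallel fixation screws for fractures of the distal
    acromion from a watertight bone surface mesh. Casts parallel rays along
    candidate viewing axes to map the safe corridor (the projected region a
    straight screw can traverse through one continuous segment of bone),
    optimizes the viewing axis over a cone around the anatomical long axis,
    splits the corridor evenly into medial and lateral halves, fits the
    maximal inscribed screw in each half, and measures entry-point distances
    to anatomical landmarks and angles against the superior reference plane.
    Includes a parametric generator of acromion-like solids with known ground
    truth for validation, and a statistical layer that summarizes cohorts and
    compares sexes with two-sample t tests, including t tests recomputed
    directly from published group summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    grDevices,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
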