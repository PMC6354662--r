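Package: nasovol
Title: Nasal Airway Segmentation and Volumetry for CBCT Volumes
Version: 0.1.0
Authors@R:
    person("Nasovol", "Developers", email = "nasovol@example.org", role = c("aut", "cre"))
Description: Semi-automatic segmentation and volumetric measurement of the nasal
    airway space in cone beam computed tomography (CBCT) volumes. Implements a
    five-step pipeline (grayscale smoothing, air thresholding, a landmark-defined
    region of interest bounded by two coronal planes and a spline roof, geometric
    "blocking" of sinus connections, and seeded region growing with
    voxel-calibrated volume read-out), a connectivity-based rule that selects the
    highest threshold keeping an enclosed cavity disconnected from outside air,
    watertight surface-mesh export to STL with an independent divergence-theorem
    volume oracle, a synthetic digital-phantom generator with analytically known
    cavity volumes for accuracy validation, and the reliability statistics
    (paired t-test, intraclass correlation, random error of paired differences)
    used to appraise repeated airway measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
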