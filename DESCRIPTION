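Package: ptvflow
Title: Particle Tracking Velocimetry and Gaussian Process Flow Mapping for Ventricular Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies slow fluid flow in time-lapse grayscale movies (for
    example optical coherence tomography B-scan sequences of cerebrospinal
    fluid in embryonic brain ventricles) by particle tracking velocimetry.
    The pipeline detects sub-resolution bright particles with a
    Laplacian-of-Gaussian detector, links them into trajectories by
    gap-closing linear-assignment tracking, fits a velocity vector per
    sub-second trajectory window by weighted least squares, and reconstructs
    a dense, spatially smooth velocity field with per-pixel uncertainty by
    Gaussian process regression. Compartmental summaries (median speed,
    cross-sectional area), exact-distribution nonparametric group
    comparisons, temporal colour-coded polarity projections and line
    kymographs with a ciliary beat-frequency readout are included, together
    with a synthetic movie generator with exported ground truth so that
    every stage can be verified by parameter recovery against known flow.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mgcv,
    tiff,
    png,
    jsonlite,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
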