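Package: coroflow
Title: Stochastic Coronary Arterial Trees and Myocardial Blood-Flow Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Organ-scale simulator of the human coronary arterial vasculature.
    Generates stochastic Strahler-ordered binary arterial trees (orders 6-11)
    from morphometry statistics, embeds them in an idealized truncated-ellipsoid
    biventricular anatomy with a self-avoidance/boundary-avoidance space-filling
    algorithm, solves steady-state Poiseuille network blood flow under pressure
    boundary conditions, and quantifies myocardial perfusion heterogeneity
    (relative dispersion, fractal dimension, transmural profiles) on ensemble
    averaged voxel blood-flow maps. Includes virtual experiments: inlet pressure
    sweeps, single-segment stenosis, and order-wise vessel blocking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
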