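Package: lungwater
Title: Pulmonary Proton-Density MRI Simulation, Reconstruction and
    Quantitation with Cardiac and Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for ultrashort-echo-time (UTE) proton-density
    ("lung water") MRI. Provides a spoiled gradient-echo signal model with a
    Bloch-equation simulator, digital sponge and axial-thorax phantoms with a
    rigid exercise-motion model, golden-angle radial-out k-space simulation,
    density-compensated Kaiser-Bessel gridding reconstruction with a
    spoke-consistency motion-rejection stage, lung region-of-interest
    quantitation (rest/stress change, Bland-Altman agreement, phantom
    linearity experiments), cardiac volume-time-curve metrics (peak diastolic
    filling rate, chamber summaries, PCr/ATP saturation and blood-contamination
    corrections), and the cohort statistics used to link myocardial energetics
    to exercise-induced pulmonary congestion (Jonckheere-Terpstra ordered
    trend, exact Wilcoxon signed-rank, Kruskal-Wallis with Dunn post hoc,
    Pearson regression, and bias-corrected bootstrap mediation), plus a
    synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    RNifti,
    optparse
Config/testthat/edition: 3
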