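Package: zharpstrain
Title: Three-Dimensional Myocardial Strain Analysis from Tagged Cardiac MR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for three-dimensional regional
    myocardial strain from z-encoded tagged (zHARP-style) cardiac MR.
    Provides a ground-truthed left-ventricular phantom (analytic deformation,
    complex tagged-image synthesis, late-gadolinium-enhancement volumes, and a
    segment-level strain sampler calibrated to published infarct data),
    harmonic-phase extraction and material-point tracking, per-pixel
    Green-Lagrange strain tensors with directional and principal
    decompositions, viability-driven myocardial segmentation (FWHM and n-SD
    infarct delineation, chordwise transmurality, infarct/adjacent/remote
    segment models), global left-ventricular function metrics, and a
    logistic-regression/ROC model-comparison engine with DeLong paired tests
    for quantifying the incremental diagnostic value of 1D, 2D and 3D strain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
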