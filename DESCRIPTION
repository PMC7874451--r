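Package: morpholong
Title: Longitudinal 3D Geometric Morphometrics of Dense Facial Quasi-Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for longitudinal geometric-morphometric analysis of spatially
    dense 3D surface quasi-landmarks, built around repeated-measures facial
    imaging studies. Provides template-based quasi-landmark mapping (anchor
    similarity alignment, thin-plate-spline warping, closest-surface
    projection), symmetric-component Generalized Procrustes Analysis,
    distance-matrix permutational MANOVA with restricted (within-subject)
    permutations and partial R-squared, per-landmark localization with heatmap
    mesh export, Procrustes-variance (morphological disparity) comparisons for
    shape and form, and a synthetic longitudinal cohort generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
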