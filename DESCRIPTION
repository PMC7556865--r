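Package: aosloflow
Title: Immune-Cell Dynamics and Single-Vessel Hemodynamics from Label-Free
    Retinal Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies immune-cell motility and single-vessel blood flow from
    label-free adaptive-optics scanning-light-ophthalmoscope (AOSLO) retinal
    videos. Provides frame registration and de-sinusoiding, temporal averaging,
    heat-map cell detection (a trainable filter-bank regressor and a classical
    difference-of-Gaussians detector), nearest-neighbour track linking with
    quality control, displacement and confinement-ratio motility metrics,
    kymograph (space-time image) red-blood-cell velocimetry with cardiac-cycle
    averaging, motion-contrast lumen diametry, volumetric flow rates, and
    longitudinal arteriole-versus-venule flow-conservation analysis. A synthetic
    video and kymograph generator with exact ground truth makes the whole
    pipeline testable end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
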