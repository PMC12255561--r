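Package: fairasl
Title: Quality Assurance for Multi-TI FAIR Arterial Spin Labeling Liver
    Perfusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for respiration-aware acquisition planning, inversion-
    recovery T1 mapping, perfusion quantification and residual-based quality
    control of multi-inversion-time FAIR (flow-sensitive alternating
    inversion recovery) arterial spin labeling experiments in ventilated
    small animals. Includes a respiratory-cycle model for planning
    motion-free inversion times, per-voxel bounded least-squares fitting of
    the inversion-recovery signal model, perfusion maps from paired
    selective/global T1 maps, residual (MSE) maps with corrupted
    inversion-time detection and exclusion-and-refit, edge-overlay motion
    inspection, ROI statistics with histogram and FWHM analysis, and a
    digital rat-liver phantom with injectable respiration and pulsation
    corruption for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
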