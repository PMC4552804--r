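Package: cervelast
Title: Shear-Wave Elastography and Collagen Fibre Directionality Analysis of Cervical Ripening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for longitudinal cervical-ripening studies:
    region-of-interest stiffness quantification from shear-wave elastography
    (shear-wave-speed to Young's modulus conversion, replicate aggregation,
    artefact rejection by within-ROI dispersion, dataset accounting), collagen
    fibre directionality from second-harmonic-generation microscopy (tile
    stitching, 2D Fourier spectra, moment-ellipse fitting, the minor/major axis
    ratio R, brightest-pixel intensity), and the study statistics (rank-based
    ANOVA-type statistic for the two-group repeated-measures design, per-time
    rank-sum tests with step-up correction, Bland-Altman limits of agreement,
    Kruskal-Wallis, quadratic trajectory fits). A synthetic-data generator
    emulates the study design (stiffness trajectories, within-ROI dispersion
    with designed quality-control violations, fibrous textures of controllable
    alignment) so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
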