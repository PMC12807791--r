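Package: rhsp
Title: Automated Lesion Signal-to-Noise Analysis for Random Hypoechoic
    Sphere Phantom Ultrasound Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of freehand cine-loop scans of a random
    hypoechoic sphere phantom (RHSP) for ultrasound quality assurance.
    Stacks B-mode frames into a volume, denoises and bias-corrects it,
    segments the 2 mm hypoechoic spheres with a depth-adaptive
    mirrored-background threshold, splits touching spheres with a seeded
    3D watershed on the distance transform, measures the lesion
    signal-to-noise ratio (LSNR) of every sphere at its maximum
    elevational cross-section, and aggregates LSNR-versus-depth curves
    with uncertainties and repeatability statistics. A speckle phantom
    simulator with known ground truth makes the whole pipeline testable
    without a scanner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    tiff,
    RNifti,
    splines,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
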