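Package: drls
Title: Dynamically Regulated Localized Level-Set Segmentation of 3D Tumor Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Three-dimensional localized region-based level-set segmentation of
    low-contrast tumor volumes in which the energy-functional weights, the
    initialization, and the per-point local-window radius are regulated over
    the iterations by a three-class contour-position classifier (a small 3D
    convolutional network, or a deterministic geometric oracle). Includes a
    synthetic tumor-phantom generator at volume-of-interest scale, uniform
    modeling and mean-separation localized energies with reaction-diffusion
    stabilization of the level-set field, the standard volumetric overlap and
    surface-distance evaluation metrics (DICE, VOE, RVD, ASD, RMSD), NIfTI
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
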