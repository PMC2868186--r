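Package: cryostack
Title: Reconstruction, Visualization and Morphometry of Block-Face Cryo-Imaging Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-acquisition toolkit for tiled block-face cryo-imaging of small
    animals: white-card flat-field correction, tile mosaicking with feathered
    overlap blending and cross-correlation refinement, phase-correlation stack
    alignment, RGB colour-ratio feature detectors with step opacity transfer
    functions, semiautomatic organ segmentation with signed-distance slice
    interpolation, bricked multiresolution volume access, voxel-count volumetry
    with body-weight and brain-volume normalization, multiplanar reformatting
    with bone morphometry, and a minimal true-colour orthographic volume
    compositor. A seeded synthetic phantom generator with analytic ground truth
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
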