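Package: spinemorph
Title: 3D Dendritic Spine Detection, Segmentation and Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Headless pipeline for detecting dendritic spines in 3D
    fluorescence microscopy stacks and measuring their morphology. A
    dendrite reconstruction in SWC format is rasterized as a chain of
    spheres joined by conical frustums; spine heads are found as 3D
    intensity local maxima inside a configurable distance band around
    the dendrite border, grown into 3D objects from the intensity
    distribution around each maximum, and connected back to the shaft
    by intensity-weighted optimal-path neck tracing. Per-spine head
    volume and surface, neck length, stubby/necked type and per-dendrite
    spine density are reported. Includes a synthetic phantom generator
    (anisotropic Gaussian PSF, Poisson and Gaussian noise) with exact
    ground truth for validation, coordinate-based replayable editing of
    seeds and segmented heads, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
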