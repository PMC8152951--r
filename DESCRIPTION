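Package: cortexmosaic
Title: Spatial Organization of Labeled Neurons in Cortical Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial organization of immunolabeled neuronal
    populations in cortical sections. Detects somata in fluorescence image
    stacks (median projection, difference-of-Gaussians enhancement, CLAHE,
    automatic thresholding, watershed, particle selection), registers
    detections to manually annotated cortical layers, and characterizes
    their arrangement with laminar densities and fractions, nearest-neighbor
    distance regularity (coefficient of variation), double-positive merging,
    and a kernel-smoothed pair correlation function with translation edge
    correction and Monte-Carlo envelopes under complete spatial randomness.
    Includes generators for ground-truth point processes (Poisson, Matern
    type II hard-core, Thomas cluster) in layered windows and a renderer
    producing fluorescence-like synthetic stacks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
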