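Package: fluidmorph
Title: Interstitial Flow, Morphogen Gradients, and Epithelial Morphometrics
    for Microfluidic Hydrogel Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for microfluidic epithelial-morphogenesis
    experiments in collagen-filled tissue chambers. Simulates hydrostatic-head
    driven Darcy flow and advection-diffusion morphogen transport in a
    homogenized 2-D device model; estimates convective interstitial fluid
    velocity from FRAP image sequences by centroid tracking; quantifies
    collagen fiber orientation (structure tensor, angle histograms, and the
    alignment coefficient); and measures cyst/organoid morphology from binary
    masks (area, perimeter, aspect ratio, roundness, shape factor, protrusion
    angles, and the top/bottom contour-curvature ratio). Ships seeded
    synthetic-data generators with ground truth so every stage is verifiable
    without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
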