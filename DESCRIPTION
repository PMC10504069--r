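Package: endoshear
Title: Wall Shear Modelling and Image-Based Quantification of Endothelial
    Flow Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models steady laminar flow in the rectangular channels of a
    96-well fluidic plate (plane-Poiseuille operating-point conversions,
    Fourier-series rectangular-duct solution, finite-difference cross-section
    solver) and quantifies endothelial flow responses from multi-channel
    fluorescence images: axial cell and nucleus orientation via circular
    statistics on doubled angles, nucleus-to-Golgi front-rear polarity with
    globally optimal organelle pairing, per-nucleus marker intensity, and
    relative qPCR expression by the 2^-ddCq method with standard-curve
    efficiency. Ships a seeded synthetic-monolayer image generator with
    per-cell ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    clue,
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
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
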