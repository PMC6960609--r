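Package: cmer
Title: Compound Micro-Expression Recognition from Magnified Facial Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for recognising basic and compound facial
    micro-expressions in short aligned face-video clips. Implements Eulerian
    video magnification (Laplacian pyramid spatial decomposition with a
    zero-phase Butterworth temporal bandpass), apex-frame localisation by
    sliding-window 3D FFT spectral amplitude, a duality-based TV-L1 optical
    flow solver with the classical pointwise threshold update, Facial Action
    Coding System (FACS) action-unit tables for 6 basic and 12 compound
    emotions with region-wise compositing of compound expression images, and
    a shallow convolutional network classifier trained on colour-coded
    optical-flow feature maps with leave-one-subject-out evaluation. A
    procedural face-video generator with action-unit parameterised sub-pixel
    motion provides fully synthetic, reproducible datasets for testing every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    png,
    signal,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
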