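Package: sonoseg
Title: Multisensory Brain MRI Tumor Segmentation with Color and Sound Rendering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for low-grade glioma segmentation on 2-D
    FLAIR MRI slices and for perceptual rendering of the results. Four
    segmentation architectures (U-Net, a DeepLab-style multi-scale encoder,
    a graph attention network, and a top-k sparse graph network) are built on
    a compact CPU reverse-mode autodiff engine included in the package, and
    trained with a soft Dice objective, plateau learning-rate scheduling and
    early stopping. Predicted masks are analysed with z-score and
    morphological statistics, and rendered as RGB color maps, stereo audio
    sonifications and Standard MIDI Files, so that tumor size, intensity,
    shape complexity and anomaly severity become visible and audible. A
    synthetic brain-phantom generator reproduces the on-disk layout of the
    patient-wise image/mask collections the pipeline consumes, making every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
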