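Package: afspectra
Title: Autofluorescence Spectral Analysis and Segmentation for
    Light-Sheet Microscopy Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-channel autofluorescence
    light-sheet fluorescence microscopy volumes of optically cleared,
    unstained tissue. Provides TIFF stack input/output with acquisition
    metadata, bilateral-illumination fusion by digital addition,
    trilinear block-average downsampling, exposure and histogram
    normalization, edge-rise-distance profiling with confidence
    intervals, per-region spectral signatures across excitation
    channels, digital subtraction and inversion channels, a Fourier
    power-spectrum sharpness statistic, trainable random-forest pixel
    classification on a multiscale 2D feature bank with probability-map
    postprocessing and DICE evaluation, and a synthetic liver/biopsy
    phantom generator with ground-truth labels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ranger,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
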