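Package: aquae
Title: Autoencoders for Low-Contrast Aquatic Monitoring Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for compressing, denoising and archiving low-contrast
    monitoring frames from aquarium video. Provides a synthetic murky-scene
    generator with ground-truth object boxes, an image preprocessing
    pipeline (quality filtering, brightness/contrast/kernel enhancement,
    rotation and shift augmentation, square zero-padding, bilinear
    resizing), symmetric multilayer-perceptron and convolutional
    autoencoders built from declarative stage specs with exact parameter
    accounting, seeded Adam training with early stopping, standardized
    difference-image denoising with Sobel treatment, RGB histogram
    distinguishability statistics, and a quantized Base64 latent-space
    store with a date/hour file layout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
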