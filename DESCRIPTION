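Package: seedcount
Title: Density-Map Seed Counting with Multi-Column Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts seeds (rice grains) in images by density-map regression.
    Converts point annotations to ground-truth density maps with fixed or
    geometry-adaptive Gaussian kernels, trains a multi-column convolutional
    network (MCNN) density regressor and an improved multi-task variant that
    fuses a count-level prior branch (spatial pyramid pooling plus a count-bin
    classifier) into a x4-upsampling density head, and evaluates counts with
    MAE, MSE and count-ratio accuracy. Includes a synthetic seed-image
    generator with exact point annotations so the full train/evaluate cycle
    runs offline, and a command-line interface for dataset synthesis, density
    generation, training, counting and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
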