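Package: schicenh
Title: Single-Cell Hi-C Contact Map Enhancement with Residual Adversarial Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputation and enhancement of sparse single-cell Hi-C contact
    maps with a deep residual-network generator trained adversarially
    against a convolutional discriminator. Provides the full data pipeline
    (cooler and triplet-text input/output, binomial read down-sampling,
    clip-and-scale normalisation, 40x40 patch cropping and full-matrix
    assembly), the four-term generator loss (pixel MSE, perceptual feature
    loss, total-variation smoothing, adversarial term) with a binary
    cross-entropy discriminator loss, CPU training with Adam, and an
    evaluation suite covering MSE/PSNR/SSIM/SNR image metrics,
    insulation-score TAD boundary comparison, and a random-walk
    concordance score for Hi-C reproducibility. A synthetic single-cell
    Hi-C generator with power-law distance decay, planted TADs and loops
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rhdf5,
    stats,
    utils,
    yaml,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
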