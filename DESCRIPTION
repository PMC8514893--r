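Package: rrednet
Title: Recursive Residual Encoder-Decoder Denoising for Low-Dose CT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for removing Gaussian noise and streak artifacts from
    low-dose computed-tomography images with a shallow recursive residual
    encoder-decoder network. Includes a synthetic phantom and degradation
    simulator producing paired clean/noisy images, PSNR and SSIM image
    quality metrics, a small CPU trainer for the residual codec, recursive
    application of the trained model with input cascading, and
    summary-statistic group comparisons (pooled and Welch t-tests from
    mean/SD/n, 2x2 chi-square tests, rounded event rates) for clinical
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
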