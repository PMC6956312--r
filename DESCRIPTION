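Package: dearct
Title: Deep Encoder-Decoder Adversarial Restoration of Few-View CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for few-view (sparse-view) computed tomography
    restoration with the DEAR family of deep encoder-decoder adversarial
    networks. Provides a seeded generator of CT-like 3D phantom volumes with
    inter-slice continuity and low-contrast lesions, a slice-wise fan-beam
    forward projector and filtered back-projection for simulating few-view
    acquisitions, a normalization and 3D patch-stack pipeline, builders for the
    DEAR-3D generator and its 2D variants together with a 3D Wasserstein
    critic, the composite MSE + SSIM + adversarial objective with WGAN-GP
    training, and PSNR/SSIM/RMSE evaluation with sliding-window whole-volume
    inference. The convolutional engine (forward/backward passes, transpose
    convolutions, gradient-penalty double backpropagation, Adam) is implemented
    in C++ via Rcpp/RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
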