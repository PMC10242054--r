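Package: vtsnn
Title: Fully Spiking Neural Networks for Image Denoising with Bit-Plane
    Spike Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for image reconstruction with virtual-temporal spiking
    neural networks. Provides a lossless bit-plane spike codec
    (undistorted weighted encoding/decoding, UWE/UWD) together with the
    lossy time-to-first-spike (TTFS) and membrane-potential (MPD)
    comparison codecs, discrete-time integrate-and-fire (IF) and leaky
    integrate-and-fire (LIF) neuron dynamics with surrogate gradients, a
    fully spiking U-net denoiser, two surrogate-gradient training regimes
    (independent-temporal and spatio-temporal backpropagation), a
    synthetic data generator with Gaussian noise corruption, PSNR/MSE
    metrics, and a spike-counting energy model for comparing spiking and
    conventional networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
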