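Package: niddl
Title: Supervised Deep Denoising for Volumetric Fluorescence Neuro-Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compact fixed-channel encoder-decoder convolutional networks for
    denoising volumetric fluorescence recordings of neurons, trained on small
    sets of temporally independent noisy/clean image pairs and applied
    frame-independently to calcium-imaging videos. Includes synthetic
    whole-brain scene and semi-synthetic video generators with known
    ground-truth traces, Poisson-Gaussian noise simulation, classical
    median/Gaussian baselines, image-quality metrics (RMSE, PSNR, SSIM) with
    min-max normalization, Gaussian-mixture nuclei segmentation, trace
    extraction and accuracy statistics, body-curvature correlation analysis,
    and morphological neurite segmentation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
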