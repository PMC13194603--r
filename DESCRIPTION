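Package: mvdenoise
Title: Unpaired Multi-View Low-Dose CT Denoising by Knowledge Transfer
Version: 0.1.0
Authors@R:
    person("mvdenoise", "maintainers", email = "mvdenoise@example.org",
           role = c("aut", "cre"))
Description: A two-stage framework for denoising low-dose computed tomography
    (CT) volumes without paired training data. Three view-independent
    unpaired image-translation models (CycleGAN-style, least-squares
    adversarial training) are trained on axial, sagittal and coronal slices
    of unpaired low-dose and high-dose volumes. Their view-complementary
    predictions are fused per pixel by cycle-consistency weighting into
    pseudo-targets that supervise a single axial-view student denoiser, so
    that inference needs one 2D model only. Includes a synthetic anisotropic
    CT phantom generator with projection-domain Poisson noise insertion
    (parallel-beam radon transform and filtered back-projection), a compact
    CPU neural-network engine (convolution, transposed convolution, instance
    normalisation, Adam) built on 'RcppArmadillo', and PSNR/SSIM/RMAE
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
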