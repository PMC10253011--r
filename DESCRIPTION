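Package: plaquevae
Title: Variational-Autoencoder Tissue Classification of Peripheral Arterial
    Occlusions from Multi-Contrast MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised classification of peripheral arterial
    chronic-total-occlusion composition from co-registered multi-contrast MRI.
    Three contrasts (T1-weighted, T2-weighted, ultrashort echo time) are fused
    into pseudo-color images, compressed by a convolutional variational
    autoencoder into a two-dimensional latent space, and partitioned into four
    tissue classes (patent, partially patent, mostly occluded soft, mostly
    occluded hard) from which per-lesion tissue scores and class percentages
    are derived. Includes a synthetic vessel-phantom generator with per-slice
    ground-truth labels, a preprocessing pipeline (cohort normalization, RGB
    fusion, axial reslicing, auto-crop, resizing, hex-range wall removal), and
    an end-to-end reproducible run orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    EBImage,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
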