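Package: chirpnet
Title: Neural-Network Analysis of Bat Echolocation Soundscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for ultrasonic passive acoustic monitoring of
    bats. Recordings are cut into 1 s segments and turned into linear-frequency
    spectrograms and Mel-frequency cepstral coefficient (MFCC) matrices. A small
    convolutional autoencoder compresses spectrograms into latent feature
    vectors that are projected with UMAP to explore noise structure across
    measurement heights and location-year collections; a compact convolutional
    classifier trained on MFCCs performs bat/noise, genus and species
    identification. Includes a synthetic ultrasonic-soundscape generator
    (frequency-modulated pulse trains plus stationary and non-stationary noise)
    that emulates the statistical structure of wind-test-field monitoring data,
    evaluation harnesses for directed cross-collection validation, joined-data
    training and hybrid-class confusion analysis, and reconstruction metrics
    (PSNR, SSIM).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    uwot,
    cluster,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
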