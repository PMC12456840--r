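Package: fastshim
Title: Fast RF Shimming for Ultrahigh-Field Parallel-Transmit MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Slice-wise radiofrequency (RF) shimming for multi-channel
    transmit arrays at ultrahigh field. Implements magnitude
    least-squares shim optimization with multi-restart Adam and a
    classic variable-exchange solver, a quasi-static multi-channel
    B1+ field simulator with head-like phantoms and rotation
    augmentation, a residual convolutional network that regresses
    shim weights directly from complex field maps under a
    physics-informed loss, and a discriminator-style non-uniformity
    detector that screens shimmed magnitude maps for voids. Includes
    a reproducible end-to-end pipeline, a versioned dataset
    container, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
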