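Package: dbytk
Title: Hyperspectral Detection of Non-Tobacco Related Materials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting non-tobacco related materials (NTRMs such as
    weeds, rubber rings and feathers) on a tobacco processing belt from
    hyperspectral imagery. Provides an ENVI-dialect reader/writer and
    detection-label I/O, a synthetic hyperspectral belt-scene generator,
    region-restricted principal component analysis with weight-coefficient
    characteristic-wavelength selection, pseudo-color composition and
    decorrelation contrast stretch enhancement, a rotation/background-overlay
    augmentation protocol, a trainable dual-branch anchor-free detector with a
    BiFPN-style efficient-lighting feature pyramid neck implemented on a small
    Rcpp convolution engine, and detection metrics (precision, recall, AP,
    mAP, F1) with an end-to-end pipeline driver and command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
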