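Package: polarRaman
Title: Polarized Micro-Raman Spectral Analysis and Discrimination of Breast Tissue
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for polarized micro-Raman spectroscopy of breast tissue:
    synthesis of polarized and conventional Raman spectral cohorts with
    class-specific band anisotropy, iterative modified-polynomial fluorescence
    baseline removal, trough-baseline band-area integration and band
    statistics, amide III bimodal-ratio anisotropy analysis, encoding of
    polarization-angle spectral matrices as pseudo-color images, and
    discrimination of cancerous versus normal tissue with a compact 2D
    convolutional neural network under patient-grouped cross-validation,
    alongside 1D-CNN and k-nearest-neighbour baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    png,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    class,
    knitr
Config/testthat/edition: 3
biocViews: Spectroscopy, Classification, Software
RoxygenNote: 7.3.3
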