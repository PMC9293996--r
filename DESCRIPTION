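Package: aunetseg
Title: Anisotropic 3D U-Net Segmentation of Liver Lesions in Late-Phase MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for automatic liver lesion segmentation in the
    late hepatocellular phase of dynamic contrast-enhanced liver MRI. Implements
    an anisotropic 3D U-Net with valid (unpadded) convolutions trained with a
    liver-masked Dice loss, multi-model training by successive halving over
    differently seeded runs, morphological suppression of thin false positives
    at the liver border, and a multi-rater evaluation framework with an
    uncertainty-aware segmentation score and N:M lesion correspondence
    detection metrics. Ships a synthetic liver phantom generator with simulated
    rater variability so that every stage can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    oro.nifti
Config/testthat/edition: 3
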