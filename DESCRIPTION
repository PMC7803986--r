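Package: stlseg
Title: Sequential Transfer Learning for Semantic Food Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Curriculum ("sequential transfer") training for encoder-decoder
    semantic segmentation networks. Class-prototype features are extracted
    from the bottleneck of a conventionally pre-trained U-Net, clustered
    agglomeratively, and the dendrogram is cut at its greatest link heights
    to derive a nested label hierarchy; the network is then retrained
    through progressively finer label sets with classifier-head replacement
    while all other weights are carried over. Includes ROI patch
    preparation and augmentation for tray-style food images, a compact
    trainable U-Net with a replaceable 1x1-convolution head, pixel-level
    prediction definiteness metrics, and a synthetic tray generator with a
    designed visual class hierarchy for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    mclust,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
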