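Package: maefnet
Title: Lightweight Attention Segmentation and Breast-Muscle Weight Prediction
    for Broiler Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end in vivo prediction of broiler breast-muscle weight from
    radiograph-like images. Implements MAEFNet, a lightweight encoder-decoder
    segmentation network (pruned MobileNetV3-Large encoder at output stride 16
    with attention-refinement, coordinate-attention and feature-fusion decoder
    modules) trained with cross-entropy loss and monitored with dice loss;
    a 15-descriptor shape-morphometrics extractor over binary pectoral-muscle
    masks; and a recursive-feature-elimination + linear support vector
    regression model mapping selected shape features plus live weight to
    breast-muscle weight. A synthetic phantom generator with a known
    weight-generating model makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
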