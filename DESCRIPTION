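Package: msunet
Title: Multi-Scale U-Net Blocks, Architectures and Evaluation for Binary
    Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds and trains multi-scale convolution blocks and the
    segmentation architectures derived from them. A multi-scale block runs
    parallel two-convolution branches with different kernel sizes (1, 2, 3,
    5, 7, 9; optionally dilated) over the same input and fuses them by
    concatenation or summation followed by a 1x1 reduction convolution;
    residual, serial and dilated variants are included. Blocks can replace
    the convolution blocks of a U-shaped encoder-decoder network (on either
    or both paths), of an attention-gated variant, or of a nested
    dense-skip variant, and a parameter-matched wide U-Net control is
    solved automatically. The package ships a self-contained CPU
    convolutional-network engine (convolution, batch normalization,
    max-pooling, transposed convolution, SGD with momentum), a seedable
    synthetic image/mask generator emulating four binary-segmentation
    modalities, a six-subset split with five-fold cross-validation,
    pixel-overlap metrics (IoU, Dice, precision), ROC/AUC, and paired
    statistical comparison of cross-validated results.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
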