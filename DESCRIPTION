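Package: chalkcam
Title: Weakly Supervised Detection and Quantification of Rice Grain Chalkiness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Phenotyping pipeline for chalkiness in rice grain scans. Crops
    individual grains from plate images, trains a small convolutional
    classifier to separate chalky from non-chalky grains, and uses
    gradient-weighted class activation mapping (Grad-CAM, plus the
    Grad-CAM++ and Score-CAM variants) to localize the chalky area from
    image-level labels only. Heatmaps are binarized into chalk masks and
    summarized as a per-grain chalkiness score and chalk-area percentage;
    localization is evaluated against polygon ground truth with
    intersection-over-union based metrics. A synthetic grain-image
    generator with exact ground truth makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
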