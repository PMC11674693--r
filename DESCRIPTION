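Package: stripscan
Title: Texture-Based Classification of Lateral Flow Assay Strip Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies lateral flow assay (LFA) reader images by analyte
    concentration level using averaged horizontal multi-offset gray-level
    co-occurrence matrix (AHMO-GLCM) texture features. Provides a synthetic
    strip-image generator, per-half adaptive segmentation with region-of-
    interest detection, patch extraction, 64-level quantised co-occurrence
    matrices averaged over horizontal offsets d = 1..25, a 22-feature
    Haralick-style texture vector, minimum-redundancy-maximum-relevance
    feature ranking, a small convolutional network over tabular feature
    vectors used as a feature extractor, and a battery of classical
    classifiers evaluated with micro-averaged sensitivity, specificity and
    accuracy on a stratified train/validation/test split.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    png,
    jsonlite,
    MASS,
    class,
    e1071,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    igraph,
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
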