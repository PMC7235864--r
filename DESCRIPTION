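Package: molarBoVW
Title: Bag-of-Visual-Words Classification of Third-Molar Complications on
    Panoramic Dental Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for recognising third-molar (wisdom
    tooth) complications on panoramic dental radiographs. Images pass
    through a median / bilateral smoothing and Sobel edge-detection chain,
    a fixed-coordinate region-of-interest mask restricts keypoint
    detection to the four third-molar sites, local descriptors (ORB or
    SIFT) are quantised against a K-means visual vocabulary into
    bag-of-visual-words histograms, and six classical classifiers are
    benchmarked under stratified 10-fold cross-validation. A seeded
    synthetic radiograph generator provides labelled phantom datasets so
    the full pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    nnet,
    rpart,
    e1071,
    randomForest,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
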