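Package: cordgrass
Title: Phenology-Based Mapping and Potential-Distribution Analysis of
    Invasive Cordgrass
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map the invasive salt-marsh cordgrass Spartina
    alterniflora from irregular satellite reflectance time series and to
    analyse its expansion and potential distribution. Provides a seeded
    synthetic-scene generator with class-specific phenology, cloud gaps and
    outliers; spectral indices (NDVI, EVI, LSWI, NDWI) and water frequency;
    harmonic-regression reconstruction of annual index curves with
    phenological feature extraction; random-forest classification with
    stratified validation and confusion-matrix statistics (overall,
    producer's and user's accuracy, kappa); patch-based expansion metrics
    (areas, growth rates, area-weighted centroid migration); and a
    from-first-principles maximum-entropy species-distribution model with
    variable pruning, L1-regularised fitting, importance measures, response
    curves, ROC/AUC, sensitivity-plus-specificity thresholding and
    three-tier potential zoning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    caret,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
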