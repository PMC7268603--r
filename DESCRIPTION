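Package: microsoilq
Title: Predicting Land Use and Soil Quality from Soil Bacterial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting land use, soil
    physico-chemical variables and guideline-based soil-quality categories
    from soil bacterial community composition (OTU tables). Provides
    rarefaction and replicate averaging, Bray-Curtis dissimilarity and
    PERMANOVA with pairwise tests, Ward clustering with multi-criteria cut
    selection, specificity-fidelity indicator OTU selection, probabilistic
    PCA of soil chemistry with missing values, stratified random-forest
    classification and regression with permutation importance, and
    conversion of predicted variables into soil-quality categories. A
    synthetic-data generator with known ground truth supports
    parameter-recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    cluster,
    MASS,
    randomForest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
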