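Package: pinephenomics
Title: UAV Multispectral Phenotyping and Genetic Evaluation for Slash Pine Orchards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for canopy phenotyping of slash pine
    breeding orchards from drone multispectral imagery. Generates synthetic
    orchard trials (layout, family-structured traits, trait-linked
    reflectance, rendered surface/terrain/band rasters), detects and
    delineates individual tree crowns from canopy height models, computes
    sixteen vegetation indices, fits and compares machine-learning
    predictors (PLSR, SVM, GBM, RF) of needle nitrogen and nonstructural
    carbohydrate content, and estimates REML variance components,
    narrow-sense heritability, and family breeding values per month for
    bivariate family selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    e1071,
    randomForest,
    xgboost,
    mixOmics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
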