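Package: frontierness
Title: Positive-Deviance Frontier Analysis of Gridded Cropland Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling gridded cropland extent and expansion with
    balanced-subsample logistic regression ensembles, deriving a "frontierness"
    score as standardized deviations from a global null model of cropland
    extent, classifying positive/negative deviance regions, measuring
    proportional overlap enrichment between deviance classes and expansion
    maps, and comparing expansion models with and without the frontierness
    covariate. Includes a synthetic-landscape generator with planted frontier
    clusters so the full pipeline can be exercised and validated against known
    ground truth, plus plain-text (ESRI ASCII) raster input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    readr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
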