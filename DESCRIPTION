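Package: cpirank
Title: Conservation Priority Index for Ranking Waterbodies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a country-scoped, area-penalized Conservation Priority
    Index (CPI) for ranking lakes and other waterbodies for site-based
    conservation. Combines species relative rarity within a country, IUCN
    Red List threat weighting, and surface area as a cost proxy. Ships an
    occurrence-record cleaning pipeline with per-stage retention accounting,
    descriptive statistics (Pearson correlations, rank-sum group comparison
    with effect size, species accumulation curves), tree-ensemble
    classifiers (random forest and gradient boosting) with variable
    importance and partial dependence, and a seeded synthetic-data
    generator so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    vegan,
    randomForest,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
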