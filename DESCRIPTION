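Package: soilNDEP
Title: Fidelity of Variation Sources in Air-Dried Soil Microbial Archives
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies how faithfully air-dried soil archives preserve the
    source of variation in soil microbial community structure. For every pair
    of sampling plots the package measures the explanation proportion (EP) of
    the spatial factor by pairwise PERMANOVA on Bray-Curtis dissimilarities,
    computed separately for fresh and air-dried states, and summarises the
    loss of explanatory power with the normalised difference explanation
    proportion (NDEP). Downstream analyses relate NDEP to spatial distance and
    environmental difference: Spearman correlations, Jenks natural-breaks
    scale classes, variation partitioning, exhaustive best-subset regression
    on environmental-difference predictors, and paired differential abundance
    of prevalent OTUs. A synthetic-data generator provides paired
    fresh/air-dried community tables with known ground truth, so that the
    whole pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    geosphere,
    jsonlite,
    biomformat
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
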