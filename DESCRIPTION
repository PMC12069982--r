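Package: nutriclass
Title: Hybrid Metaheuristic Clustering and Fuzzy Gradient Boosting for
    Child Nutritional Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying child nutritional status (stunting,
    wasting, severe wasting, underweight, overweight) from anthropometric
    and socioeconomic indicators.  Implements the Fire Hawk Optimizer, a
    population metaheuristic for box-constrained minimization; FHO-driven
    k-means clustering with silhouette-based selection of the cluster
    number; and EGBF, a second-order gradient-boosted tree classifier
    whose split selection is modulated by fuzzy entropy over triangular
    low/medium/high feature memberships.  Includes a synthetic-data
    module generating child-level cohorts under WHO z-score label rules
    and country-level prevalence tables with controllable cluster
    structure, min-max normalization, stratified train/test splitting,
    one-vs-rest evaluation metrics, and an end-to-end seeded pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
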