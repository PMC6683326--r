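Package: ecogroupr
Title: Discovery of Temporally Conserved Covarying Taxon Groups in
    Longitudinal Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies sparse groups of bacterial taxa ("ecogroups") whose
    pairwise covariance is conserved across time in longitudinal
    relative-abundance surveys. Monthly taxon-taxon covariance matrices are
    normalized, binarized at their extreme deciles, averaged over months,
    and eigendecomposed; taxa with extreme first-principal-component
    projections under a fitted generalized extreme value distribution form
    the ecogroup. Also provides iterative-PCA detection of the age at which
    community structure stabilizes, sample ordinations with cohort
    centroids, a sparse random-forest model of microbiota age, strain-level
    metabolic-module enrichment analyses, and a fully parameterized
    synthetic-data generator with planted covariance structure for
    validation.
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
    igraph,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    biomformat,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
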