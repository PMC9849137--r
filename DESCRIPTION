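Package: cotrack
Title: Behavioral Classification of Immune-Cell Tracks in Organoid Co-Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn time-lapse tracking exports from engineered
    T cell / tumor-organoid co-cultures into quantitative behavior. Tracks
    are interpolated, cut to fixed windows and binarized, compared with a
    multivariate dynamic-time-warping cross-distance, embedded and
    clustered into named behavioral signatures, and new experiments are
    classified with a random forest over track descriptive statistics.
    Companion modules quantify organoid killing kinetics from dead-cell
    dye, correlate killing with cluster-specific T cell engagement through
    a sliding-window Pearson correlation, and map behavioral signatures
    onto transcriptomic clusters ordered in pseudotime via probability
    transitivity. A seeded synthetic co-culture simulator with known
    ground truth supports testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
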