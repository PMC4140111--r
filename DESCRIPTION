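Package: elmanet
Title: Cluster-Wise Elman Network Classification with Partial Least Squares Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised classification for small, correlated tabular data sets
    (for example agronomic risk forecasting from weather covariates) by an
    optimized Elman recurrent network pipeline. Features are compressed with
    NIPALS partial least squares, with the number of latent components chosen
    by K-fold cross-validated PRESS; training samples are partitioned into
    subclasses by UPGMA hierarchical clustering on Mahalanobis distances; one
    Elman network expert is trained per subclass with batch
    Levenberg-Marquardt; new samples are routed to the nearest subclass
    centre and recognized by that subclass's expert. Baseline variants
    (plain BP and Elman networks, PCA- and PLS-reduced networks,
    cluster-only networks) and a benchmark harness are included, together
    with a synthetic-data generator that reproduces the statistical
    structure the method targets: redundant correlated features, latent
    low-dimensional signal, and cluster substructure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
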