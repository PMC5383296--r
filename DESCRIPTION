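Package: vsratio
Title: Training-Ratio Design for Machine-Learning Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation harness for studying how the inactive-to-active
    (IN/A) training ratio and the screening-library size jointly determine
    the performance of ligand-based virtual screening classifiers. Curates
    heterogeneous activity records (Ki, pKi, IC50) to a common Ki scale,
    represents compounds as binary fingerprints, generates synthetic
    chemotype-structured active and decoy populations, sweeps a grid of
    training ratios by library sizes by trials for several classifiers,
    scores every cell with recall, precision and the Matthews correlation
    coefficient, and recommends a minimal cost-effective training ratio via
    an MCC-loss threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    grid,
    stats,
    utils,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    rpart,
    randomForest,
    jsonlite
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
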