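Package: adipomorph
Title: 3D Morphometry of Adipocytes in Cleared Adipose Tissue Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying adipocyte morphology in three-dimensional
    light-sheet volumes of cleared, lipid-stained adipose tissue. Provides a
    seeded synthetic tissue-phantom generator with exact ground truth, a
    classical segmentation pipeline (intensity thresholding, circular opening,
    distance-transform watershed separation of touching cells), per-cell 3D
    shape features (volume, equivalent diameter, surface area, sphericity,
    nearest-object distance), and group-level statistics (mean and SEM
    summaries, Mann-Whitney comparisons, binned size distributions with
    false-discovery-rate control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    yaml,
    tiff,
    xml2,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
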