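Package: stromasig
Title: Stromal Gene-Signature Discovery from Two-Color Microarrays with
    Survival Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline from spot-level two-color microarray data to
    a prognostic stromal gene signature. Covers spot quality filtering and
    log-ratio formation, presence and variability filters,
    mock-referenced zero-transformation, 10-nearest-neighbour imputation,
    permutation-based significance analysis of microarrays (two-class,
    multiclass and block-permutation designs with fudge-factor and
    delta/FDR calibration), uncentered-Pearson average-linkage
    hierarchical clustering, cell-type-specific fold-change signature
    derivation, cross-platform signature mapping by Unigene cluster,
    centroid scoring with median split, and Kaplan-Meier / univariate Cox
    survival stratification. Ships a synthetic-data generator with planted
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
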