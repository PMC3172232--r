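Package: painmvpa
Title: Cross-Subject Decoding of Painful Heat from fMRI Activity Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-voxel pattern analysis pipeline for deciding whether a
    thermal stimulus was painful from block-design BOLD fMRI data, trained on
    one group of subjects and evaluated on held-out groups. Provides a seeded
    synthetic-cohort generator that emulates a 40 s baseline / 30 s heat block
    design with planted sub-percent pain-responsive regions; per-stimulus
    percent-signal-change extraction with gray-matter and artifact feature
    reduction; a linear soft-margin support vector machine with signed
    decision values; per-subject accuracy/PPV/NPV summaries with one-sample
    t-tests against chance; distance-from-hyperplane confidence rejection
    with exclusion curves and cubic fits; label-permutation null
    distributions for voxel-weight significance maps; and sphere
    region-of-interest classifiers.
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
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
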