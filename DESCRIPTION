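Package: oaraudit
Title: Automated Auditing of Auto-Segmentation Editing in Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing how deep-learning auto-segmentation (DLAS)
    contours of organs at risk are edited before clinical approval in
    radiotherapy. Compares DLAS and final approved structure masks with the
    surface Dice similarity coefficient at a physical distance tolerance,
    detects contours used unedited (voxel-exact identity), aggregates results
    per organ and per calendar time period, tracks trends, and flags outlier
    cases whose editing falls outside the usual range. Includes a synthetic
    cohort generator that emulates characteristic editing behaviour (margin
    growth, longitudinal cropping, local surface edits) with parameters that
    drift over time, so the whole audit pipeline can be exercised without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    dplyr,
    tibble,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
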