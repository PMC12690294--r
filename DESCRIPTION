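Package: tauspread
Title: Individualized Network-Based Modeling of Tau Spread
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling the spread of tau pathology along structural
    brain connectomes at the level of the individual participant. Converts
    regional tau-PET SUVR to a tau pathology index (TPI) via per-region
    Gaussian-mixture models, detects individualized tau epicenters by
    within-subject outlier analysis, computes shortest-path connectivity
    distances on weighted structural connectomes, and fits and compares four
    cross-sectional and longitudinal regression models that cross
    individualized versus canonical epicenters with individual versus group
    connectomes. Includes a fully specified synthetic cohort generator with
    known ground truth so the complete pipeline can be exercised and validated
    without access-controlled imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    lme4,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
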