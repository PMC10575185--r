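Package: maldisort
Title: Machine-Learning Dichotomous Sorting of MALDI-TOF Peak Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dichotomous (two-class) sorting of samples from
    MALDI-TOF centroid peak lists: fixed-bin m/z feature extraction with
    per-range tolerances, binary or intensity feature encodings,
    gradient-boosted decision-tree trial grids with diagnostic evaluation
    (sensitivity, specificity, Youden index, ROC scatter), a mass-dependent
    signal-attenuation and digestion-enhancement model, and a synthetic
    generator of intact versus tryptically digested bacterial spot spectra
    for end-to-end benchmarking of the workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
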