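Package: hsikmeans
Title: Hyperspectral Microscopy Phantoms and K-Means Detection of Ductal Carcinoma
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for semi-automated detection of ductal carcinoma in situ
    (DCIS) in hyperspectral microscope images of histology slides. Provides an
    ENVI-format reader/writer for hyperspectral reflectance cubes, a synthetic
    phantom generator that emulates patient cohorts of stained and unstained
    normal-duct and DCIS tissue, region-of-interest spectral summarization and
    discriminative wavelength selection, a from-scratch K-means pixel
    classifier with Euclidean assignment and zero-reassignment stopping,
    leave-one-patient-out training and testing, confusion-matrix metrics
    (sensitivity, specificity, TNR, FPR), and a command-line interface for the
    full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
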