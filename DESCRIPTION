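Package: imrtqa
Title: Patient-Specific IMRT QA Metrics for Collapsed and Rotated Deliveries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intensity-modulated radiotherapy (IMRT)
    verification measurements performed in a water phantom with a Farmer-type
    ionization chamber. Computes plan complexity scores (modulation complexity
    score and its leaf-sequence and aperture-area components), dose-volume
    histogram metrics over the chamber volume (homogeneity index, conformity
    index), the fraction of beams intersecting the chamber, combined per-beam
    statistical uncertainty, and the Alfonso-formalism small-field output
    correction factor kQclin with its application to chamber readings. Plans
    are read from DICOM-RTPLAN or a JSON fixture dialect; dose grids from
    DICOM-RTDOSE or a plain-text raster format. A deterministic divergent-
    aperture toy dose engine and seeded plan generator reproduce the paired
    rotated/collapsed delivery study design on synthetic cohorts end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
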