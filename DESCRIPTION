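Package: maizestand
Title: Maize Stand Detection and Plant-Spacing Estimation from Plot-Scale UAV Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects individual maize plants in low-altitude nadir RGB imagery
    of field plots and estimates within-row plant-to-plant spacing. Plants are
    segmented with the excess-green (ExG) vegetation index, cleaned with
    relative area and shape filters, and fragmented plants are merged by a
    morphological dilation rule. Object centroids are corrected for the
    parallax displacement of elevated canopies away from the nadir point,
    assigned to crop rows by an iterative buffer-averaging line fit, and
    projected onto the row line to obtain adjacent-plant distances. The
    package includes detection and spacing accuracy metrics (precision,
    recall, mean absolute distance agreement and relative error with
    exclusion of intervals touching false positives or negatives), plot-level
    stand statistics, and a synthetic aerial scene simulator that renders
    plots with exactly known plant positions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
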