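Package: srsquant
Title: Semi-Quantitative Analysis of Somatostatin Receptor and Salivary
    Gland Scintigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of planar nuclear-medicine images for
    inflammation imaging: target-to-background (T/B) ratio measurement over
    polygonal regions of interest, the 0-5 ordinal joint/gland uptake scale
    with two-reader averaging and per-patient aggregation (number of
    positive regions, global score, severity index), salivary-gland
    time-activity curve analysis with stimulated-secretion uptake and
    functional scores, and pre/post-therapy cohort statistics (paired and
    unpaired t tests, regression, table builders).  Includes a Poisson
    phantom generator with analytic ground truth for static joint images
    and dynamic sialoscintigraphy, a synthetic cohort simulator, readers
    for a documented plain-text fixture dialect and for planar
    nuclear-medicine DICOM objects, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
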