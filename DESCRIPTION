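Package: hidpipe
Title: Spatial Proximity Analysis of Multiplex Immunofluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated analysis pipeline for multiplex immunofluorescence
    regions of interest: linear spectral unmixing, rule-based pixel-level
    tissue quality masking with a 30 percent useful-tissue inclusion gate,
    watershed nuclear segmentation with 2 micron cell expansion, percentile
    rescaling and single-threshold marker scoring, the Hypothesised
    Interaction Distribution (HID) cell-cell proximity statistic, and
    stratified survival analysis (Kaplan-Meier with Greenwood variance,
    Mantel-Haenszel log-rank, univariate Cox regression). Includes a
    synthetic-data generator that emulates clustered immune-cell point
    patterns, rendered multichannel images with artifacts, and
    proportional-hazards survival outcomes, so the full pipeline is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    survival,
    pracma,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
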