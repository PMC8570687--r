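Package: periglia
Title: Automated Detection, Classification and Quantification of
    Fluorescently Labeled Pericytes and Microglia in Brain Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying fluorescently labeled cells in
    multi-channel (DAPI/DsRed/GFP) whole brain-section images: tissue and
    large-vessel pixel classification with morphological cleanup, watershed
    detection of DAPI-stained nuclei with fixed-width cell expansion,
    intensity-threshold classification of pericytes (DsRed) and microglia
    (GFP) into a four-way class partition, grid-sweep optimization of
    detection and classification thresholds against manual counts via the
    percent-difference metric, and per-region density and percentage
    quantification. Includes a synthetic-section generator with exhaustive
    ground truth so every stage can be validated without slide-scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
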