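Package: herbsheet
Title: Automated Metadata Extraction from Digitised Herbarium Specimen Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning digitised herbarium sheet images into structured
    specimen metadata. The package locates the mounted scale bar by normalised
    cross-correlation template matching, derives the effective image resolution
    (DPI) from the matched scale, detects printed text regions with a
    line-contrast profile, restricts optical character recognition to those
    regions through a pluggable engine interface, and extracts typed entities
    (scientific names, collector and determiner names, dates, geographic
    coordinates, localities) from the recognised text using dictionaries,
    a gazetteer and regular expressions. Results accumulate in a per-specimen
    description file (JSON) with a full provenance log, and three composable
    workflows (pre-OCR, OCR, extraction) chain the services over batches of
    sheets. A synthetic sheet generator with complete ground truth makes every
    stage testable without real specimens or an OCR binary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
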