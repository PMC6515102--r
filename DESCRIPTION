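Package: qamsr
Title: Single-Marker Multi-Component Quantification and HPLC Fingerprint
    Analysis for Herbal Quality Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality-evaluation workflow for multi-component herbal
    medicines from chromatographic data: linear calibration curves with
    signal-to-noise based detection and quantification limits,
    external-standard quantification, quantitative analysis of
    multi-components by single marker (QAMS) via relative correction
    factors, method-validation statistics (relative standard deviation,
    spike recovery, paired agreement testing), fingerprint peak detection
    with multipoint retention-time correction and similarity scoring
    against a consensus reference chromatogram, hierarchical clustering of
    standardized peak-area profiles, and a seeded generator of synthetic
    chromatograms for end-to-end verification. Ships the published
    reference tables of a 21-batch Gastrodia elata tuber study as
    checksummed plain-text fixtures and reproduces their derived
    statistics in one call.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    pracma,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
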