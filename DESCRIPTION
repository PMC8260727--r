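Package: epestage
Title: Quantitative Extraprostatic Extension Measurement and pT3a Substaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative assessment of extraprostatic extension
    (EPE) in radical prostatectomy specimens and for three-tier substaging
    of pT3a prostate cancer. Implements planar measurement of EPE foci
    (radial distance, circumferential length, 2D square area, contour shape
    class) from capsule and tumor contours, focus counting by tumor-nodule
    identity, the pT3a1/pT3a2/pT3a3 substage classifier driven by radial
    distance and focus number, circumferential-margin combined grouping,
    C-index guided cut-off scanning, and survival statistics (Cox
    proportional hazards, Kaplan-Meier, Harrell's concordance) for
    biochemical-recurrence endpoints. A calibrated synthetic-cohort
    generator reproduces the marginal structure of a pT3a radical
    prostatectomy cohort under an exponential proportional-hazards model so
    that classifier behaviour and hazard-ratio recovery can be studied by
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
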