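Package: collafluor
Title: Collagen Quantification from Tissue Autofluorescence Spectra and
    Picro-Sirius Red Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for objective, non-invasive assessment of collagen during
    wound healing. Implements preprocessing of laser-induced tissue
    autofluorescence spectra (Fourier low-pass smoothing, two-point baseline
    correction, normalization to the NADH emission maximum), quantification
    of the collagen emission at about 405 nm (peak intensity and band area
    350-405 nm), reference-color scoring of Picro-Sirius red polarized-light
    histology images in HSI color space (type I collagen = red/yellow,
    type III = green), group-level statistics (mean +/- SEM, Student's
    unpaired t-test, repeated-measures ANOVA with Bonferroni-adjusted
    per-day contrasts) and fold-change reporting. A seeded synthetic-data
    module generates two-peak spectra with group/day collagen trajectories
    and fiber images with known pixel-class fractions so that the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    png,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
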