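Package: coreshell
Title: Shell-Thickness Analysis for Core-Shell Hydrogel Capsules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of core-shell hydrogel capsules from
    transmitted-light microscopy. Implements the volumetric ionotropic-gelation
    model linking soaked calcium concentration to alginate shell thickness
    (with through-origin estimation of its proportionality constant), a
    colourimetric image pipeline (two-cluster segmentation, centre-region
    colour statistics, R-B metric), a linear colour-to-thickness calibration
    with no-shell classification and formation-threshold inference, and a
    synthetic capsule-image generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    png,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'colorimetry.R'
    'calibration.R'
    'synthetic.R'
    'pipeline.R'
    'coreshell-package.R'
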