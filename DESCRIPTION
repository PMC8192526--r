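Package: tbscreen
Title: Slide-Level TBS Classification of Cervical Liquid-Based Cytology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A slide-level diagnostic engine for cervical liquid-based
    thin-layer cytology screening under the Bethesda System (TBS, 2014).
    Encodes a 24-class cytological annotation taxonomy and its mapping to
    TBS diagnoses, fuses per-target detector, classifier, patch and nucleus
    morphometry evidence into a fixed 121-feature slide vector, and renders
    a slide diagnosis with a two-stage gradient-boosted decision (a
    sensitivity-maximising any-positive cross-validation ensemble for
    squamous lesions, a subtype model, and a logical decision tree for
    infectious, glandular and endometrial lesions). Includes a digital
    pathology image quality-control gate (variance-of-Laplacian focus,
    HSI colour histograms, Otsu cellularity), ASAP XML annotation I/O,
    synthetic slide and smear-tile generators for end-to-end testing at
    desk scale, and screening performance metrics under clinical-group
    equivalence rules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xgboost,
    jsonlite,
    xml2,
    yaml,
    EBImage,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
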