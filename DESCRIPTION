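Package: retilab
Title: Annotation-Free Geometric Detection of Diabetic Retinopathy Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric, annotation-free labeling of diabetic retinopathy
    lesions on retinal photographs.  A multiscale directional contrast shape
    descriptor separates blob-like lesions (microaneurysms, hemorrhages,
    exudates) from curvilinear vessels; candidate regions are scored by the
    intensity contrast between signed-distance ring bands and bucketed into
    low/indeterminate/high confidence; high-confidence regions are typed by
    rule-based shape and texture criteria; clean image patches are mined
    around them to train per-lesion-type U-Net segmentation models without
    any manual annotation.  Includes a seeded synthetic fundus generator
    with per-lesion ground truth, overlap-based detection metrics with size
    binning, and a pure-R U-Net training and inference harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
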