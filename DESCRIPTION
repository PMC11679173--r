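Package: nailsense
Title: Fingernail Segmentation, Reference-Patch Color Normalization and
    Nail-Color Health Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Batch pipeline for fingernail color monitoring from hand images
    acquired under a guided convention: five vertical finger regions, black
    reference squares at the image corners and white reference squares along
    the top band. Extracts per-channel black/white reference levels, applies
    the linear reflectance normalization eta = (I - Black)/(White - Black),
    segments nail regions through a pluggable backend (a classical
    brightness/saturation baseline or externally produced mask files), cleans
    masks with majority filtering and square-element erosion, measures
    per-finger mean raw and normalized RGB with an append-only history,
    matches measured colors against a built-in nail-color/symptom reference
    table, evaluates segmentations with IoU and Dice loss, and generates
    seeded synthetic hand fixtures with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, Visualization, Classification
RoxygenNote: 7.3.3
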