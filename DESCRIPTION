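Package: mechanoct
Title: Mechanoregulation Analysis of Time-Lapsed Micro-CT Bone Defect Healing
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the mechanical regulation of bone defect
    healing from time-lapsed micro-computed tomography density images.
    Provides a synthetic phantom generator with a known mechanostat rule,
    multi-density threshold segmentation and formation/resorption overlays,
    automatic volume-of-interest partitioning of a femoral defect, a
    structured-grid voxel finite-element solver for effective-strain fields,
    physiological load estimation with a two-spring fixator/callus model,
    ROC association of strain with mineralisation, two-threshold surface
    remodelling classification with correct-classification-rate heat maps,
    and bone volume kinetics per density threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
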