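Package: wbrtaperture
Title: Landmark-Based Field Aperture Design for Whole-Brain Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated design of lateral-opposed field apertures for
    whole-brain radiotherapy (WBRT). Generates synthetic head phantoms with
    ground-truth structure masks, projects structures and renders digitally
    reconstructed radiographs (DRRs) in the beam's-eye-view at gantry
    90/270 degrees, derives nine anatomic landmarks (A-I) from structure
    bounding boxes under a customizable configuration (anterior-caudal line
    shapes, brain expansion margin, skin flash, C1/C2 caudal border, orbital
    inclusion), assembles the closed aperture polygon, fits multileaf
    collimator leaves, and cross-checks two independent structure sources
    (3D mask projection versus rule-based DRR segmentation) with Hausdorff
    and mean-surface-distance quality-assurance metrics inside a clinical
    evaluation region.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
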