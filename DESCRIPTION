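Package: levelpost
Title: Slice-Plane Postprocessing and Evaluation of Head-and-Neck Lymph
    Node Level Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for working with multi-class head-and-neck lymph node
    level label volumes from CT autosegmentation pipelines. Implements
    slice-plane adjustment postprocessing (per-slice majority resolution of
    craniocaudally exclusive levels and boundary-slice trimming),
    largest-connected-component cleanup, left-right mirroring augmentation
    with label adaption, Otsu-based CT foreground masking, geometric
    accuracy metrics (volumetric Dice, surface Dice at a tolerance, maximum
    Hausdorff distance), the paired nonparametric comparison protocol used
    to evaluate such segmentations, a blinded-rating manifest generator,
    and a synthetic neck phantom generator so the whole pipeline can be
    exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
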