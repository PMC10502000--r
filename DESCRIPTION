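Package: gutgaze
Title: Gaze-Based Bowel Annotation, Tubular Reconstruction, and Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for converting gaze-recorded centerline annotations of the
    gastrointestinal tract into volumetric segmentations and bowel-diameter
    parametric maps, for simulating CT-like tubular phantoms with exact ground
    truth, for preparing and augmenting model-ready samples, for training a
    small dual-output U-net that predicts a 3-part gut segmentation together
    with a per-voxel bowel diameter, and for quantifying repeatability and
    agreement with Dice scores, two-way-agreement intraclass correlation, and
    Bland-Altman 95% limits of agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
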