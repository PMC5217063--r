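Package: minwaves
Title: Pattern Analysis of Min-Protein Dynamics in Confined Microchambers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify MinD/MinE reaction-diffusion patterns in
    time-lapse fluorescence movies of fully confined microchambers:
    synthetic ground-truth movie generation (traveling waves, spiral
    rotations, pole-to-pole and striped oscillations), field rotation
    correction and chamber segmentation, quadrant summaries (snapshot,
    temporal-STD image, midline kymographs), deterministic phase-map
    pattern classification, wavelength and front-velocity estimation from
    kymographs, GFP-referenced protein concentration inference, and
    aggregation of per-chamber results into geometric phase diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    pracma,
    minpack.lm,
    EBImage,
    tiff,
    png,
    yaml,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
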