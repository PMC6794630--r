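Package: bbbperm
Title: Solute Transport Simulation and Permeability Estimation for a
    Microfluidic Blood-Brain Barrier Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for a five-channel microfluidic model of
    the blood-brain barrier (BBB) co-cultured with 3D neural cells. Provides
    a finite-difference solver for Fick's second law on the heterogeneous
    device plan view (amyloid-beta secretion, material-specific
    diffusivities, a low-diffusivity endothelial barrier, scheduled medium
    replacement), a synthetic fluorescence time-lapse generator for the
    FITC-dextran influx assay with known ground-truth permeability, and the
    control-volume intensity estimator that converts the gel-side intensity
    rise into a permeability coefficient in cm/s. Includes cohort simulation
    and the two-sample comparison used to contrast wild-type and
    Alzheimer's-disease barriers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
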