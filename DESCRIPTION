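Package: dectspr
Title: Dual-Energy CT Tissue Decomposition and Proton Stopping-Power Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scanner-calibrated stoichiometric CT-number prediction, an
    expandable human-tissue reference basis, voxelwise elemental-composition,
    electron-density, mass-density and proton stopping-power-ratio (SPR)
    estimation from dual-energy CT, a single-energy (Schneider-style HLUT)
    comparator, region-of-interest composition statistics, and range-based
    SPR ground truth from multi-layer ionization chamber depth-dose curves.
    Includes a synthetic phantom generator so every pipeline stage can be
    validated end-to-end against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
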