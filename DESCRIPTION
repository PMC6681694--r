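Package: RepeatQuant
Title: Test-Retest Repeatability of Quantitative PET and Diffusion Tumor
    Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for quantitative-imaging test-retest studies of
    solid tumors: reads 3D PET and apparent-diffusion-coefficient (ADC)
    volumes with binary tumor masks (NIfTI), converts PET activity
    concentration to SUV and lean-body-mass-adjusted SUL (James formula,
    F-18 decay correction), extracts tumor metrics (SUV_max, SUL_peak via
    a 1-cm3 sphere search, 40% isocontour, metabolic tumor volume, total
    lesion glycolysis, ADC median/trough), matches effective uptake times
    between paired list-mode acquisition windows, and computes
    Bland-Altman repeatability statistics (percent differences,
    within-subject coefficient of variation, repeatability coefficient,
    limits of repeatability) with rank-based comparisons under
    Benjamini-Hochberg false-discovery-rate control. Includes synthetic
    phantom and cohort generators with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
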