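Package: relloi
Title: Cross-Sectional ADC Profile Analysis of Ring-Enhancing Brain Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of apparent diffusion coefficient (ADC) maps of
    ring-enhancing brain lesions via line-of-interest (LOI) profiling.
    Samples ADC values along a line crossing the lesion compartments
    (perilesional edema, enhancing ring, core), segments the profile at six
    landmarks (A-F), extracts gradient and plateau features, compares lesion
    groups with nonparametric tests, and classifies lesions (glioblastoma
    versus abscess) with k-nearest-neighbours and a Gaussian-kernel support
    vector machine. Includes a synthetic ring-enhancing-lesion phantom
    generator with known ground truth for validation, readers and writers for
    NIfTI and plain-text rasters plus JSON/CSV annotations, and an end-to-end
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    RNifti,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
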