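Package: phasetex
Title: Simulation and GLCM Texture Staging of X-Ray In-Line Phase-Contrast Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for propagation-based (in-line) X-ray
    phase-contrast imaging of stomach-like specimens and texture-based
    cancer staging. Generates stage-labelled refractive-index phantoms
    (delta/beta maps), simulates coherent projection images by Fresnel
    free-space propagation with Poisson noise, builds sinograms and
    reconstructs tomographic slices by filtered back projection, extracts
    nine gray-level co-occurrence matrix (Haralick) texture features from
    randomly sampled regions of interest, performs correlation-matrix
    principal component analysis with a cumulative-contribution-rate
    component rule and an (F1+F2) threshold discriminant, and evaluates a
    linear support vector machine stage classifier by k-fold
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
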