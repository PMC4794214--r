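Package: stereoisa
Title: Binocular Complex-Cell Models Learned by Independent Subspace Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns binocular complex-cell models from stereo image patches
    using Independent Subspace Analysis (ISA) and characterizes their
    disparity selectivity.  Provides a seeded generator of naturalistic
    synthetic stereo image pairs, the patch sampling and per-eye
    centring/normalisation pipeline with PCA whitening, a maximum-likelihood
    ISA fitter with orthonormal components grouped into two-subunit
    subspaces, energy and max-pooling complex-cell response rules, 2D Gabor
    fits of subunit receptive fields, sine-grating phase-phase and bar
    shift-shift response maps, disparity tuning curves with sinusoid fits,
    the Disparity Discrimination Index (DDI), tuned-excitatory /
    tuned-inhibitory / near / far symmetry classification, and bootstrapped
    population summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
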