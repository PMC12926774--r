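Package: spinalcompcor
Title: PCA-Derived Nuisance Regressors for Spinal Cord fMRI Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven denoising for spinal cord fMRI. Builds a noise region
    of interest outside the spinal cord and cerebrospinal fluid by in-plane mask
    dilation, extracts slice-wise voxel timeseries and computes principal
    components by singular value decomposition, and selects how many components
    to retain with a parallel analysis against IAAFT (iterative amplitude
    adjusted Fourier transform) surrogate timeseries. Also provides the
    surrounding modeling stack: RETROICOR cardiac and respiratory regressors,
    cerebrospinal-fluid and motion nuisance regressors, discrete-cosine
    high-pass filtering, voxel-wise general linear models with nested and
    omnibus F-tests, temporal signal-to-noise ratio, Dice overlap, spatial
    Spearman agreement, and slice-wise seed connectivity, plus a synthetic
    cord phantom generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
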