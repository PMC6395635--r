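Package: enlivr
Title: Calibrationless Parallel MRI Reconstruction by Extended Nonlinear
    Inversion with Multiple Coil-Profile Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint estimation of image content and smooth coil sensitivity
    profiles from undersampled multichannel k-space data using the iteratively
    regularized Gauss-Newton method (IRGNM) on a relaxed bilinear SENSE-type
    forward model with k sets of maps (ENLIVE; the k = 1 case is NLINV).
    Includes Cartesian and non-Cartesian (radial, gridded non-uniform FFT)
    data paths, generators for the sampling geometries used in calibrationless
    imaging studies (regular, variable-density Poisson-disc, CAIPIRINHA,
    partial Fourier, radial), a synthetic-data module (numerical phantoms,
    smooth coil models, limited field-of-view aliasing, virtual conjugate
    coils, phase singularities, calibrated noise), a tiny-instance lifted
    convex solver with nuclear-norm regularization for testing the low-rank
    equivalence theory, and BART-style CFL file interchange with a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    Matrix,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    RNifti,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
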