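Package: glymadc
Title: Apparent Diffusion Coefficient Estimation from CSF Tracer Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates region-wise apparent diffusion coefficients (ADC) of a
    cerebrospinal-fluid tracer from multi-time-point concentration fields on a
    labeled brain-like mesh by PDE-constrained optimization. Provides a P1
    finite-element solver for the diffusion initial-boundary-value problem with
    time-varying Dirichlet boundary control, discrete-adjoint gradients of the
    regularized data-misfit objective, quasi-Newton estimation of per-region
    diffusivities together with the optimal boundary concentration history,
    a synthetic verification study with known ground truth and uniform vertex
    noise, voxel-image preprocessing (signal-to-concentration conversion,
    CSF-value projection, Gaussian smoothing, image-to-mesh sampling), and
    tortuosity/DTI comparison arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    RNifti,
    graphics,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
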