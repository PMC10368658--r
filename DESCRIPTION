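Package: cassir
Title: Coded Aperture Snapshot Spectral Imaging Simulation, Reconstruction
    and Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for coded aperture snapshot spectral imaging (CASSI) of
    the retina: the mask-shear-sum forward model with exact adjoint, an
    augmented-Lagrangian/ADMM reconstruction with pluggable denoising
    priors (total variation, wavelet soft-thresholding, a trainable
    spectral-attention denoiser) and deep-unfolding training of the
    penalty schedule, prism dispersion and spatial/spectral resolution
    calibration, oxyhemoglobin-style absorption-spectrum analysis, and
    synthetic scene generators (rainbow sweep, resolution bars, eye
    phantom with a vessel absorber) so the whole pipeline runs without
    instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
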