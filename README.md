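# cassir

Coded aperture snapshot spectral imaging (CASSI) for retinal imaging, in R:
the forward model, an augmented-Lagrangian/ADMM reconstruction with
pluggable priors and deep-unfolding training, dispersion and resolution
calibration, and oxyhemoglobin-style absorption-spectrum analysis — all
runnable on synthetic scenes, with no instrument data required.

## The problem

Spectral imaging of the retina must be snapshot: the eye moves too fast for
scanning spectral cameras. A CASSI fundus camera captures the full spectral
datacube $f(x, y, \lambda)$ in one exposure by placing a random binary
coded mask $T(x, y)$ at an image plane and a dispersive prism behind it.
Each band is modulated by the mask, sheared laterally by the
wavelength-dependent dispersion $D(\lambda)$, and summed on the detector:

$$y = \Phi f + g,$$

where $\Phi$ is the mask–shear–sum operator and $g$ is detector noise.
Reconstruction inverts this underdetermined system with a prior, by ADMM:
a denoising step (the prior), a closed-form projection step
$f^i = (\gamma_2 I + \gamma_1\Phi^T\Phi)^{-1}[\lambda_2 + \gamma_2 v^i +
\Phi^T(\gamma_1 y - \lambda_1)]$ made one-shot by the diagonal structure of
$\Phi\Phi^T$, and dual multiplier updates. Fixing the iteration count at
four and training the penalties and denoiser weights end to end gives the
deep-unfolded variant (`train_unfolded()`).

The package is aimed at computational-imaging researchers who want a
self-contained, tested reference implementation of the CASSI operator
algebra, the ADMM/unfolding solver and the associated calibration and
spectral-analysis rules.

## Worked example

Simulate an eye-phantom snapshot, reconstruct it, and recover the vessel
absorption peaks:

```r
library(cassir)
w <- default_band_grid(32L)            # 445-600 nm, 5-nm bands
phantom <- eye_phantom_scene(64, 64, w, seed = 0)
mask <- random_binary_mask(64, 64, fill_fraction = 0.5, seed = 0)
op <- sensing_operator(mask, c(64, 64, 32),
                       dispersion = default_dispersion(), wavelengths = w)
op
#> <sensing_operator> scene 64 x 64 x 32 -> measurement 64 x 132

noise <- noise_model("gaussian", sigma = 0.01 * max(phantom$cube$data), seed = 1)
y <- forward_project(phantom$cube, op, noise)

cfg <- solver_config(n_iterations = 50, denoiser = denoiser("tv"), strength = 0.1)
rec <- cassi_reconstruct(y, op, cfg, wavelengths = w)
round(psnr(rec, phantom$cube), 2)
#> [1] 27.61

S_r <- field_average_spectrum(rec, phantom$vessels)
S_a <- absorption_spectrum(S_r, spectrum(w, rep(1, 32)))
find_absorption_peaks(S_a)[1:2]
#> [1] 540 575
```

The measurement is 132 columns wide because the prism shears the 32 bands
by up to 68 pixels across the 64-column scene. The reconstruction reaches
27.6 dB PSNR from a single noisy snapshot, and the normalized-difference
absorption spectrum of the vessel pixels peaks at 540 and 575 nm — the
oxyhemoglobin signature painted into the phantom.

Calibration works straight from the packaged dispersion table:

```r
as.numeric(average_spectral_resolution(default_dispersion(), feature_px = 2))
#> [1] 5
```

A command-line wrapper is installed at `exec/cassi` with `simulate`,
`reconstruct`, `calibrate` and `spectra` subcommands; every run is
reproducible from its `--seed`.

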