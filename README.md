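# mslinescan

Reflectance estimation for multishot linescan multispectral cameras under
time-varying illumination, with a full synthetic acquisition simulator and a
crop/weed pixel-classification harness.

## The problem

Linescan ("multishot") multispectral cameras build one spectral image from
many successive frames: a matrix sensor covered by narrow Fabry-Perot filter
stripes advances by one stripe height `v` between frames, so **every
(row, band) pair of the assembled cube is measured at its own frame time**.
Outdoors, the illumination `E_t(λ)` changes between frames. The radiance
measured at pixel `p` in band `b` is

    I_p^b = Q( τ ∫ E_{t(b, y_p)}(λ) · R_p(λ) · A_p(λ) · T_b(λ) dλ )

with `R_p` the surface reflectance, `A_p` the lens attenuation (vignetting),
`T_b` the filter's spectral sensitivity, `τ` the integration time and `Q`
the quantizer. Because the acquisition time `t(b, y)` depends on both the
band and the image row, classical reflectance estimators that divide by a
single white-reference spectrum (assuming constant illumination) are biased
as soon as the light changes mid-scan — which matters when the reflectance
spectra feed a crop/weed classifier that must be illumination-invariant.

The package implements this formation model end to end and a family of
estimators on top of it:

| method | reference read from | illumination assumption |
|--------|---------------------|-------------------------|
| `ref`  | full-field white cube, pixel-wise | constant |
| `wa`   | mean over a white square (WS)     | constant |
| `ms`   | per-band scene maximum            | constant + white object |
| `rw`   | **row-wise** white-diffuser border statistic | arbitrary per frame |
| `dwd`  | WD border rescaled via a second reference (WP) | varying |
| `wn`   | Wiener transform learned on ColorChecker patches | as trained |

The row-wise (`rw`) estimator divides each pixel by the median of the `m`
highest white-diffuser values *of its own image row and band*:

    R̂_rw,p^b = ρ_wd · Ĩ_p^b / median_m{ Ĩ_WD, y_p^b }

Numerator and denominator share the acquisition time, so the frame-level
illumination cancels exactly (up to quantization) no matter how it varies
between frames.

Around the estimators the package provides: ENVI-style cube I/O, a
synthetic-scene generator with known ground truth (patch charts, vegetation
scenes, illumination trajectories, radial vignetting), flat-field vignetting
correction, spectral correction to "virtual" bands with negative-value
removal, MAE / spectral-angle evaluation with an exhaustive learning/test
patch-split search, and NDVI vegetation segmentation plus QDA and
gradient-boosted-tree pixel classification with inverse-class-size weighted
metrics.

## Worked example

```r
library(mslinescan)

cfg    <- sensor_config(B = 16, v = 5, W = 128)
scene  <- make_patch_scene(h = 60, w = 128, cfg, n_patches = 12, seed = 1)
nT     <- time_map(60, cfg)$n_frames
illum  <- make_illumination("linear_drift", nT, cfg, amplitude = 0.2)
cube   <- simulate_acquisition(scene, illum, atten = NULL, cfg)
cube
#> <radiance_cube> 60 x 128 px, 16 bands (475.1-901.7 nm), tau=1076.84, quantized

rw <- estimate_rw(cube, scene$masks$wd, rho_wd = cfg$rho_wd, m = 11)
wa <- estimate_wa(cube, scene$masks$ws, rho_wd = cfg$rho_wd)
```

Comparing the per-patch mean spectra against the scene's ground truth with
`mae()` and `angular_error()` prints:

```
rw: MAE = 0.014%  spectral angle = 0.0008 rad
wa: MAE = 1.895%  spectral angle = 0.0030 rad
```

Under a ±20% linear illumination drift the row-wise estimate stays at the
quantization floor while the white-average estimate absorbs the drift as a
row-dependent scale error two orders of magnitude larger.

A command-line front end wrapping the same functions lives at
`inst/cli/mslinescan.R` (subcommands `simulate`, `vignetting`, `estimate`,
`evaluate`, `segment`, `classify`).

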