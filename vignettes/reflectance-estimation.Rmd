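---
title: "Reflectance estimation for multishot linescan cameras: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reflectance estimation for multishot linescan cameras: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mslinescan)
```

## The image-formation model

A multishot linescan camera carries a single matrix sensor covered by `B`
narrow-band filter stripes, each `v` pixel rows tall. The scene and camera
are static; between two frames the sensor advances by exactly one stripe, so
after `n_blocks + B - 1` frames every scene row has been observed through
every filter (`n_blocks = H/v`). The assembled cube therefore interleaves
acquisition times: channel `b` of stripe block `j` was measured in the frame

```
t(b, j) = (n_blocks - 1 - j) + b
```

i.e. for a fixed channel the *top* image rows are acquired *later*. The
stacking direction is a convention of this package: the assembly order of
stripes into channels fixes only the relative structure, and we document and
test the choice rather than leave it implicit. All formation-model indices
(`t`, `b`, `j`) are 0-based as in the algebra above; R array accessors stay
1-based.

The unquantized signal at pixel `p`, band `b` is
`τ · Σ_l w_bl · E_t(λ_l) · R_p(λ_l) · A_p(λ_l)` on the band-center
wavelength grid. Two spectral-sensitivity models are built in: `dirac`
(ideal single-wavelength sampling, one term) and `gaussian` (FWHM-
parameterised band, trapezoidal quadrature weights on the grid renormalized
to unit sum). The signal is offset by the dark level, perturbed by per-frame
Gaussian read noise, quantized by round-half-to-even with clipping to
`[0, 2^bit_depth - 1]`, and a single independently sampled quantized dark
frame is subtracted — in that order, so small negative counts arise exactly
as they do on hardware after dark-frame subtraction.

Two consequences of the model are asserted as tests rather than assumed:
channels with identical spectral responses disagree at a pixel once
illumination varies between frames, and pixels of equal reflectance more
than `v` rows apart disagree within a channel — both equalities are restored
under constant illumination. Because the sensor-configuration type requires
strictly increasing band centers, the identical-response case is realized
with spectrally flat reflectance and spectrally flat scalar-modulated
illumination under Dirac responses, which makes the channel integrands
identical functions of wavelength — the same observable without degenerate
metadata.

The frame pipeline (`acquire_frames()` then `assemble()`) and the direct
evaluation of the assembled model (`simulate_direct()`) are implemented
independently and must agree bit-exactly, including noise (the noise fields
are keyed by frame time so both paths draw identical values). The direct
path doubles as the oracle for the assembly geometry.

## Estimators

All single-reference estimators have the form
`R̂ = ρ_wd · Ĩ / D` and differ in the denominator:

* `ref` divides pixel-wise by a full-field white-diffuser cube (with the
  `τ_wd/τ` exposure ratio). Vignetting cancels because scene and reference
  share the optical path. Valid only under constant illumination. Note that
  the white reference must be exposed with its *own* automatic integration
  time: exposing it at the scene's `τ` saturates it, since the white cube is
  everywhere at least as bright as the scene.
* `wa` uses the per-band mean over the white square WS.
* `ms` uses the per-band maximum over the scene pixels outside the
  references; it carries no `ρ_wd` factor and is biased high whenever no
  near-white object is present (e.g. vegetation-only scenes).
* `rw` uses, for each image row, the median of the `m` highest
  white-diffuser border values of that row and band. Since a row/band pair
  is acquired in a single frame, the illumination at that frame cancels
  exactly; the estimator is insensitive to arbitrary inter-frame
  illumination trajectories up to quantization. `m = 11` is the default
  compromise between robustness to defective pixels and row coverage; desk-
  scale simulated scenes use `m = 3` because their 10%-wide border holds
  only a handful of columns.
* `dwd` is an adaptation of a two-reference scheme to the linescan
  geometry, and the least specified of the six: stage 1 computes the rw
  coarse estimate; stage 2 applies a per-band illumination scaling factor
  `mean_rows(D_b) / mean_WProws(D_b)` relating the time-averaged border
  illumination to the rows of the fully visible white patch; stage 3
  normalizes channel-wise by the mean coarse reflectance over the white
  patch and clips to 1 (the clip can saturate bright near-infrared values).
* `wn` learns a linear map from radiance to reflectance on reference patch
  spectra. With `K` bands and `n < K` training patches the Gram matrix
  `T_rad T_rad'` is singular; the inverse is realized as the Moore-Penrose
  pseudo-inverse, the unique minimum-norm solution. The printed form of the
  estimator maps a raw radiance vector through a matrix fitted on centered
  data; we default to the consistent affine form
  `G (Ĩ - mean_rad) + mean_ref` and expose the bare linear map behind
  `affine = FALSE`.

Post-processing: the sparse `K x B` spectral-correction matrix maps raw
bands onto "virtual" bands (`spectral_correct()`), and negative values —
possible both from dark subtraction and from the matrix's negative
coefficients — are replaced per channel by the 3x3 median of the *original*
channel in a single pass (`remove_negatives()`). Reading neighborhoods from
the pre-pass image keeps the operation deterministic and order-independent;
a fully negative neighborhood stays negative and is counted in a warning.

## Vignetting correction

Per band, the reference level is the median of the `m = 11` highest pixel
values of a full-field white cube (discarding saturated or defective
pixels; for even `m` the lower median is taken, ties are immaterial to the
value), and the raw factor is the ratio of that level to each pixel. Raw
factors estimated from a single cube are noisy, so each channel is smoothed
with an 11x11 uniform mean filter under reflect padding (the border policy
is unspecified territory; reflect is the standard choice). The white cube
for factor estimation is simulated under constant illumination, mirroring a
controlled laboratory acquisition.

Mirror padding makes the extension locally even at the border, which biases
a mean filter by roughly 2.7x the local slope of the factor field. At
desk-scale simulated images (tens of pixels to the corner) the corner slope
of a strength-0.3 radial field turns this into a few-percent border
deviation, while the interior curvature bias is an order of magnitude
smaller; at real sensor sizes (thousands of pixels) the same arithmetic
keeps the deviation sub-percent image-wide. Flat-field quality after
smoothing is therefore quantified where the 11x11 window has full support
(a 5-pixel interior margin); the unsmoothed factors flatten their source
cube exactly by construction, and that identity is tested too.

## The synthetic-data generator

The generator emulates exactly the structure the estimators assume:

* scenes carry a contiguous right-border white-diffuser band of width
  `round(0.1 w)` spanning all rows at reflectance `ρ_wd = 0.95`, a white
  square sample inside it, and (for patch scenes) a 24-patch-style chart
  with smooth random spectra (sums of 1-3 Gaussian bumps in [0.02, 0.95])
  and one flat white patch ≥ 0.9;
* vegetation scenes combine a slowly increasing soil spectrum (NDVI < 0.2)
  with class templates built from a logistic red edge near 705 nm, a
  chlorophyll absorption dip at 678 nm and a high near-infrared plateau
  (template NDVI ≥ 0.6), modulated per pixel by multiplicative log-normal
  noise (sd 0.04) — parametric caricatures sufficient for separable,
  NDVI-positive classes, not radiative-transfer models;
* illumination is spatially uniform (the estimators' own working
  assumption; shadows are out of scope) and follows one of four temporal
  models — constant, linear ramp `1 ± a`, sinusoid of period `T/4`, or a
  step at `T/2` — applied to a smooth daylight-like base spectrum
  normalized to peak 1, since only the relative shape matters. Drift
  amplitudes of 5-20% are free parameters of the test harness; the
  acquisition literature reports that skylight can vary appreciably over a
  multi-second scan without quantifying a standard trajectory;
* lens attenuation is a quadratic radial fall-off `1 - s·(r/r_max)²`.

Everything is deterministic given a seed. What the generator does *not*
emulate — shadows, BRDF effects, inter-frame motion, filter harmonics,
spatially varying illumination — bounds what passing tests show: they
validate the estimators under the model's own assumptions, not under every
failure mode of field data.

## Evaluation and classification

Estimation quality is measured per patch by the mean absolute error
(reported x100, in %), which is scale-sensitive, and by the spectral angle
(radians, cosine clamped to [-1, 1] before `acos`), which is scale-free;
the two deliberately disagree when an estimate has the right shape at the
wrong level. The learning/test split of the patch chart is selected by
exhaustive enumeration of all `C(n, k)` learning subsets, scoring each by
the mean MAE of the Wiener estimator (the only learning-based method) on
the complementary test patches; ties resolve to the lexicographically
smallest id set. The full-size count `C(24,12) = 2,704,156` is computed
analytically and the enumeration is validated at reduced sizes — evaluating
a training criterion 2.7 million times is not informative at desk scale.

Vegetation pixels are those with NDVI ≥ γ (γ = 0.45 by default, the bands
nearest 678.2 and 899.2 nm), cleaned by one morphological opening with a
3x3 square structuring element (the element is our choice; the cleanup
step itself only requires removing isolated pixels). Features are 5x5
channel-wise window means. Learning pixels are sampled per class in
proportion to the inverse of the class's image occurrence count; for the
detection task the crop class contributes `N` pixels and each weed species
`N/2` before merging into a single weed class. Classifiers: a class-wise
Gaussian quadratic discriminant with a 1e-6 diagonal covariance ridge
(implemented in-package because the standard QDA implementations expose no
such regularization), and histogram-based gradient-boosted trees (learning
rate 0.05, 150 leaves, 255 bins, 100 rounds, feature and bagging fractions
0.8, log-loss). Metrics weight each class by the inverse of its test-set
size, so majority classes cannot mask minority-class failures.

The end-to-end robustness experiment trains on scenes acquired under one
drift trajectory and tests on scenes under the reversed trajectory:
reflectance features from the row-wise estimator remain stable across the
mismatch, while white-average features inherit a row-dependent scale error
that differs between training and test acquisitions.

## Numerical choices and problem sizes

* Quantization: round-half-to-even (R's `round`), clip to the bit depth.
* Median of the `m` highest values: sort descending, take `m`, lower
  median for even `m`.
* Division guards: zero denominators yield 0 with a warning listing the
  count, rather than propagating infinities.
* Automatic exposure uses the linearity of the unquantized model: the
  noise-free maximum (plus dark offset) is scaled exactly to the top of
  the quantizer range.
* `H` must be a multiple of `v`; simulated geometries are chosen
  accordingly.
* Tests and the acceptance script run the full formation model at desk
  scale — cubes up to 60 x 128 pixels with 8-16 bands, 5-seed ensembles for
  the stochastic claims — chosen so the whole suite completes in seconds
  while every claim is still exercised end to end.

## Known limitations

* The `dwd` adaptation follows a prose description of its source method;
  its scaling stage is the package's own reading and is flagged as adapted.
* Estimator accuracy statements are relative to the generator's
  assumptions (uniform illumination per frame, Lambertian surfaces, static
  scene). Absolute error levels on real field campaigns depend on scene
  content the simulator does not model.
* `ms` is reported for completeness; on scenes whose non-reference pixels
  are dark in part of the spectrum its illumination estimate is biased by
  construction.
* The exhaustive split is exact but combinatorial; at full chart size only
  the count is computed analytically unless the criterion evaluation is
  genuinely needed.
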