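# Shared fixtures: a desk-scale sensor and simulation shortcuts. All
# fixtures are generated in code; image sizes are kept small so the full
# formation model runs in milliseconds.

t_cfg <- function(B = 8L, v = 5L, W = 64L, bit_depth = 10L, rho_wd = 0.95,
                  ssf_model = "dirac", fwhm = 6) {
  sensor_config(B = B, v = v, W = W, bit_depth = bit_depth, rho_wd = rho_wd,
                ssf_model = ssf_model, fwhm = fwhm)
}

# Simulate a scene acquisition; returns scene, illumination, cube and the
# matching separately exposed white cube (the white reference is acquired
# with its own exposure, like on the real system).
sim_setup <- function(cfg, h = 40L, w = 64L, scene_seed = 3L,
                      illum_model = "constant", amplitude = 0,
                      atten_strength = 0, dark = dark_model(),
                      scene = NULL, reverse = FALSE) {
  if (is.null(scene))
    scene <- make_patch_scene(h, w, cfg, n_patches = 6L, seed = scene_seed)
  nT <- time_map(h, cfg)$n_frames
  illum <- make_illumination(illum_model, nT, cfg, amplitude = amplitude,
                             reverse = reverse)
  atten <- if (atten_strength > 0) make_attenuation(h, w, cfg, atten_strength)
           else NULL
  tau <- auto_exposure(scene, illum, atten, cfg, dark)
  cube <- simulate_direct(scene, illum, atten, cfg, tau, dark)
  white_scene <- make_white_scene(h, w, cfg)
  tau_wd <- auto_exposure(white_scene, illum, atten, cfg, dark)
  white_cube <- simulate_direct(white_scene, illum, atten, cfg, tau_wd, dark)
  list(scene = scene, illum = illum, atten = atten, cfg = cfg,
       tau = tau, cube = cube, white_cube = white_cube)
}

# Mean absolute error (in %) of an estimated reflectance cube against the
# scene truth over the non-WD scene pixels.
scene_mae <- function(est, scene) {
  px <- !scene$masks$wd
  nB <- dim(est$values)[3]
  100 * mean(abs(est$values - scene$reflectance)[rep(px, nB)])
}

# NDVI of a single spectrum on a band-center grid (independent oracle for
# the image-level ndvi()).
spectrum_ndvi <- function(spec, lam, red_nm = 678.2, nir_nm = 899.2) {
  red <- spec[which.min(abs(lam - red_nm))]
  nir <- spec[which.min(abs(lam - nir_nm))]
  (nir - red) / (nir + red)
}
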