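# Synthetic-data generator: ground-truth scenes (per-pixel reflectance in
# [0,1], reference-device masks, class labels), illumination time series and
# lens-attenuation fields with the statistical structure the estimators
# assume. Illumination is spatially uniform over the scene (the estimators'
# own working assumption); shadows and BRDF effects are out of scope.

#' Ground-truth scene container
#' @param reflectance `H x W x B` array of spectral reflectance in `[0, 1]`
#'   sampled at the sensor band centers.
#' @param masks A [mask_set()].
#' @param class_names Character vector naming the integer class labels.
#' @param templates Optional matrix of per-class template spectra (rows).
#' @param soil_spectrum Optional background template spectrum.
#' @return Object of class `scene_truth`.
#' @export
scene_truth <- function(reflectance, masks, class_names = character(),
                        templates = NULL, soil_spectrum = NULL) {
  if (any(reflectance < 0) || any(reflectance > 1))
    stop("reflectance must lie in [0, 1]")
  if (!identical(dim(reflectance)[1:2], dim(masks$wd)))
    stop("masks must share the reflectance H x W")
  structure(list(reflectance = reflectance, masks = masks,
                 class_names = class_names, templates = templates,
                 soil_spectrum = soil_spectrum),
            class = "scene_truth")
}

# White-diffuser border geometry shared by all generated scenes: a
# contiguous band of right-border columns covering about 10% of the width,
# spanning every row, with a small white square (WS) sample inside it.
.wd_geometry <- function(h, w) {
  wd_width <- max(1L, round(0.1 * w))
  wd_cols <- (w - wd_width + 1L):w
  side <- max(2L, min(wd_width - 2L, round(0.25 * h)))
  r0 <- max(1L, round(h / 2 - side / 2))
  ws_rows <- r0:(r0 + side - 1L)
  c0 <- wd_cols[1] + max(0L, floor((wd_width - side) / 2))
  ws_cols <- c0:(min(w, c0 + side - 1L))
  list(wd_cols = wd_cols, ws_rows = ws_rows, ws_cols = ws_cols)
}

.base_masks <- function(h, w) {
  g <- .wd_geometry(h, w)
  wd <- matrix(FALSE, h, w); wd[, g$wd_cols] <- TRUE
  ws <- matrix(FALSE, h, w); ws[g$ws_rows, g$ws_cols] <- TRUE
  list(wd = wd, ws = ws, geometry = g)
}

# Smooth random reflectance spectrum: base level plus 1-3 gaussian bumps,
# clamped to [0.02, 0.95].
.random_smooth_spectrum <- function(lam) {
  base <- stats::runif(1, 0.05, 0.35)
  nb <- sample(1:3, 1)
  s <- rep(base, length(lam))
  for (i in seq_len(nb)) {
    amp <- stats::runif(1, -0.3, 0.5)
    ctr <- stats::runif(1, min(lam), max(lam))
    wid <- stats::runif(1, 40, 150)
    s <- s + amp * exp(-(lam - ctr)^2 / (2 * wid^2))
  }
  .clamp(s, 0.02, 0.95)
}

#' Generate a ColorChecker-style patch scene
#'
#' Rectangular patches with smooth random spectra laid out on a neutral
#' background, one flat white patch (reflectance >= 0.9) flagged as the
#' ColorChecker white patch (WP), a right-border white-diffuser band (WD) of
#' width `round(0.1 w)` at reflectance `rho_wd`, and a white square sample
#' (WS) inside WD. Deterministic for a fixed seed.
#'
#' @param h,w Scene height and width in pixels; `h` must be a multiple of
#'   the stripe height `config$v`.
#' @param config A [sensor_config()].
#' @param n_patches Number of patches (<= 24).
#' @param seed Integer seed.
#' @return A [scene_truth()] whose `masks$patches` labels the patches.
#' @export
make_patch_scene <- function(h, w, config, n_patches = 24L, seed = 1L) {
  if (h %% config$v != 0) stop("h must be a multiple of the stripe height v")
  if (n_patches > 24L) stop("n_patches must be <= 24")
  if (n_patches < 1L) stop("n_patches must be >= 1")
  set.seed(seed)
  lam <- config$band_centers
  B <- config$B
  bm <- .base_masks(h, w)
  scene_w <- bm$geometry$wd_cols[1] - 1L
  grid_r <- max(1L, floor(sqrt(n_patches)))
  grid_c <- ceiling(n_patches / grid_r)
  cell_h <- floor(h / grid_r); cell_w <- floor(scene_w / grid_c)
  if (cell_h < 3L || cell_w < 3L)
    stop("geometry cannot fit the requested patches")
  refl <- array(rep(0.25, h * w * B), dim = c(h, w, B))  # neutral background
  patches <- matrix(0L, h, w)
  wp <- matrix(FALSE, h, w)
  white_id <- n_patches
  spectra <- matrix(0, n_patches, B)
  for (id in seq_len(n_patches)) {
    gr <- (id - 1L) %/% grid_c; gc <- (id - 1L) %% grid_c
    mr <- max(1L, floor(cell_h / 6)); mc <- max(1L, floor(cell_w / 6))
    rows <- (gr * cell_h + 1L + mr):(gr * cell_h + cell_h - mr)
    cols <- (gc * cell_w + 1L + mc):(gc * cell_w + cell_w - mc)
    sp <- if (id == white_id) rep(0.92, B) else .random_smooth_spectrum(lam)
    spectra[id, ] <- sp
    refl[rows, cols, ] <- rep(sp, each = length(rows) * length(cols))
    patches[rows, cols] <- id
    if (id == white_id) wp[rows, cols] <- TRUE
  }
  for (b in seq_len(B)) {
    pl <- refl[, , b]
    pl[bm$wd] <- config$rho_wd
    refl[, , b] <- pl
  }
  masks <- mask_set(wd = bm$wd, ws = bm$ws, wp = wp, patches = patches)
  scene_truth(refl, masks, class_names = character(), templates = spectra)
}

# Vegetation-class template: logistic red-edge transition from a low visible
# plateau to a high near-infrared plateau, with a gaussian chlorophyll
# absorption dip near 678 nm. A parametric caricature, not a
# radiative-transfer model; classification tests only need separable,
# NDVI-positive classes.
.vegetation_template <- function(lam, vis, nir, dip = 0.03) {
  s <- vis + (nir - vis) / (1 + exp(-(lam - 705) / 12)) -
    dip * exp(-(lam - 678)^2 / (2 * 12^2))
  .clamp(s, 0.01, 1)
}

.soil_template <- function(lam) {
  0.12 + 0.13 * (lam - min(lam)) / max(max(lam) - min(lam), 1)
}

#' Generate a vegetation scene with labelled class blobs
#'
#' Background follows a slowly increasing soil spectrum (NDVI < 0.2); each
#' vegetation class is drawn from a class-specific template with a
#' chlorophyll absorption dip near 678 nm and a high near-infrared plateau
#' (template NDVI >= 0.6), modulated per pixel by multiplicative noise.
#' Class labels form blob-shaped regions; the WD border and WS sample are
#' included.
#'
#' @inheritParams make_patch_scene
#' @param classes Number of vegetation classes (>= 2).
#' @param pixel_noise Standard deviation of the per-pixel multiplicative
#'   log-normal reflectance noise. Default 0.04.
#' @param blobs_per_class Number of elliptical blobs drawn per class.
#' @return A [scene_truth()] with `masks$classes` labelling vegetation
#'   pixels (0 = soil background) and per-class `templates`.
#' @export
make_vegetation_scene <- function(h, w, config, classes = 3L, seed = 1L,
                                  pixel_noise = 0.04, blobs_per_class = 2L) {
  if (h %% config$v != 0) stop("h must be a multiple of the stripe height v")
  if (classes < 2L) stop("classes must be >= 2")
  set.seed(seed)
  lam <- config$band_centers
  B <- config$B
  bm <- .base_masks(h, w)
  scene_w <- bm$geometry$wd_cols[1] - 1L
  soil <- .soil_template(lam)
  templates <- t(vapply(seq_len(classes), function(i) {
    vis <- 0.05 + 0.015 * (i - 1)
    nir <- 0.40 + 0.07 * (i - 1)
    .vegetation_template(lam, vis, nir)
  }, numeric(B)))
  labels <- matrix(0L, h, w)
  rc <- expand.grid(r = seq_len(h), c = seq_len(scene_w))
  for (cl in seq_len(classes)) {
    for (bl in seq_len(blobs_per_class)) {
      cr <- stats::runif(1, 1, h); cc <- stats::runif(1, 1, scene_w)
      ar <- stats::runif(1, h / 8, h / 3.5)
      ac <- stats::runif(1, scene_w / 8, scene_w / 3.5)
      th <- stats::runif(1, 0, pi)
      dr <- rc$r - cr; dc <- rc$c - cc
      u <- cos(th) * dr + sin(th) * dc
      q <- -sin(th) * dr + cos(th) * dc
      inside <- (u / ar)^2 + (q / ac)^2 <= 1
      labels[cbind(rc$r[inside], rc$c[inside])] <- cl
    }
    if (!any(labels == cl)) {        # guarantee class presence
      r0 <- ((cl - 1L) %% max(1L, h - 4L)) + 1L
      labels[r0:min(h, r0 + 3L), 1:min(4L, scene_w)] <- cl
    }
  }
  refl <- array(0, dim = c(h, w, B))
  noise <- matrix(exp(stats::rnorm(h * w, 0, pixel_noise)), h, w)
  for (b in seq_len(B)) {
    pl <- matrix(soil[b], h, w)
    for (cl in seq_len(classes)) pl[labels == cl] <- templates[cl, b]
    pl <- pl * noise
    pl[bm$wd] <- config$rho_wd
    refl[, , b] <- .clamp(pl, 0, 1)
  }
  masks <- mask_set(wd = bm$wd, ws = bm$ws, classes = labels)
  scene_truth(refl, masks,
              class_names = c("soil", paste0("class_", seq_len(classes))),
              templates = templates, soil_spectrum = soil)
}

#' Generate a full-field white-diffuser scene
#'
#' Every pixel reflects with the white diffuser's factor `rho_wd`; used for
#' vignetting-model estimation and as the full-field white reference of the
#' classical estimator.
#'
#' @inheritParams make_patch_scene
#' @return A [scene_truth()] with WD covering the whole field.
#' @export
make_white_scene <- function(h, w, config) {
  if (h %% config$v != 0) stop("h must be a multiple of the stripe height v")
  refl <- array(config$rho_wd, dim = c(h, w, config$B))
  wd <- matrix(TRUE, h, w)
  scene_truth(refl, mask_set(wd = wd, ws = wd))
}

#' Generate an illumination time series
#'
#' Relative spectral power distributions `E_t(lambda)` in `[0, 1]`, one row
#' per frame time, built from a smooth daylight-like base spectrum
#' (normalized to peak 1; only the relative shape matters to the
#' estimators) under one of four temporal models.
#'
#' @param model `"constant"`, `"linear_drift"` (scalar ramp from
#'   `1 - amplitude` to `1 + amplitude`), `"sinusoid"` (scalar modulation of
#'   period `T/4`), or `"step"` (abrupt change at `T/2`).
#' @param T Number of frame times (>= 1).
#' @param config A [sensor_config()].
#' @param amplitude Modulation amplitude, in `[0, 1)`.
#' @param seed Integer seed (reserved for stochastic models; the built-in
#'   trajectories are deterministic).
#' @param reverse Logical; reverse the temporal trajectory (useful to build
#'   a test-time illumination pattern different from the training one).
#' @return Object of class `illumination_series` with fields `E`
#'   (`T x B` matrix), `band_centers`, `model`, `amplitude`.
#' @export
make_illumination <- function(model = c("constant", "linear_drift",
                                        "sinusoid", "step"),
                              T, config, amplitude = 0, seed = 1L,
                              reverse = FALSE) {
  model <- match.arg(model)
  if (T < 1) stop("T must be >= 1")
  if (amplitude < 0 || amplitude >= 1) stop("amplitude must be in [0, 1)")
  lam <- config$band_centers
  base <- 0.55 + 0.45 * exp(-(lam - 560)^2 / (2 * 160^2))
  base <- base / max(base)
  scale <- switch(model,
    constant = rep(1, T),
    linear_drift = if (T == 1) 1 else
      (1 - amplitude) + 2 * amplitude * (seq_len(T) - 1) / (T - 1),
    sinusoid = 1 + amplitude * sin(2 * pi * (seq_len(T) - 1) / (T / 4)),
    step = ifelse(seq_len(T) - 1 < T / 2, 1 - amplitude, 1 + amplitude))
  if (reverse) scale <- rev(scale)
  E <- .clamp(outer(scale, base), 0, 1)
  structure(list(E = E, band_centers = lam, model = model,
                 amplitude = amplitude),
            class = "illumination_series")
}

#' Generate a radial lens-attenuation field
#'
#' Quadratic radial fall-off `A_p = 1 - strength (r_p / r_max)^2`, identical
#' in every band; `strength = 0` yields a uniform field of ones. The
#' attenuation peaks at 1 at the optical center and is radially
#' non-increasing.
#'
#' @param h,w Field size in pixels.
#' @param config A [sensor_config()].
#' @param strength Fractional fall-off at the image corner, in `[0, 1)`.
#' @return Object of class `attenuation_field` with `A` (`H x W x B`).
#' @export
make_attenuation <- function(h, w, config, strength = 0) {
  if (strength < 0 || strength >= 1) stop("strength must be in [0, 1)")
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  r2 <- outer((seq_len(h) - cr)^2, (seq_len(w) - cc)^2, "+")
  rmax2 <- max(r2)
  plane <- if (rmax2 == 0) matrix(1, h, w) else 1 - strength * r2 / rmax2
  A <- array(rep(plane, config$B), dim = c(h, w, config$B))
  structure(list(A = A, strength = strength), class = "attenuation_field")
}
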