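# Reflectance estimators. All single-reference estimators divide the
# (vignetting-corrected) radiance by an illumination estimate derived from a
# white reference; they differ in WHERE and WHEN that reference is read:
#
#   ref - full-field white cube, pixel-wise (constant-illumination classic)
#   wa  - mean over the white square WS (constant illumination assumed)
#   ms  - per-band maximum over the scene (white-point heuristic)
#   rw  - row-wise white-diffuser border statistic; because a linescan
#         camera acquires each (row, band) pair at its own frame time, the
#         numerator and denominator of rw share the acquisition time, which
#         makes it robust to illumination variation between frames
#   dwd - rw coarse estimate rescaled through a second in-scene reference
#   wn  - Wiener (linear least-squares) transform learned on patch spectra

.div_guard <- function(num, den, what) {
  bad <- den == 0
  if (any(bad)) {
    warning(sum(bad), " zero ", what,
            " value(s); affected outputs set to 0")
    den[bad] <- Inf
  }
  num / den
}

#' Classical full-field white-reference reflectance estimate
#'
#' `R_p^b = rho_wd * (I_p^b / I_p^b[WD]) * (tau_wd / tau)`, pixel-wise and
#' channel-wise. Valid when illumination is constant over the frame
#' sequence; the shared optical attenuation of scene and white cube cancels
#' in the division, so no vignetting correction is needed beforehand.
#'
#' @param cube Scene [radiance_cube()].
#' @param white_cube Full-field white-diffuser [radiance_cube()].
#' @param rho_wd White-diffuser diffuse reflection factor.
#' @param tau,tau_wd Integration times of scene and white acquisitions
#'   (defaults taken from the cubes).
#' @return A [reflectance_cube()] tagged `"ref"`.
#' @export
estimate_ref <- function(cube, white_cube, rho_wd = 0.95,
                         tau = cube$tau, tau_wd = white_cube$tau) {
  if (!identical(dim(cube$values), dim(white_cube$values)))
    stop("scene and white cubes must share shape")
  vals <- rho_wd * .div_guard(cube$values, white_cube$values, "white cube") *
    (tau_wd / tau)
  reflectance_cube(vals, cube$band_centers, method = "ref")
}

#' White-average reflectance estimate
#'
#' Per band, the illumination level is the mean vignetting-corrected
#' radiance over the white square WS; `R = rho_wd * I / mean_WS(I)`.
#'
#' @param cube_corrected Vignetting-corrected [radiance_cube()].
#' @param ws_mask Logical `H x W` mask of the white square sample.
#' @param rho_wd White-diffuser reflection factor.
#' @return A [reflectance_cube()] tagged `"wa"`.
#' @export
estimate_wa <- function(cube_corrected, ws_mask, rho_wd = 0.95) {
  if (!any(ws_mask)) stop("WS mask is empty")
  vals <- cube_corrected$values
  d <- dim(vals)
  out <- array(0, dim = d)
  for (b in seq_len(d[3])) {
    ch <- vals[, , b]
    out[, , b] <- rho_wd * .div_guard(ch, mean(ch[ws_mask]), "WS mean")
  }
  reflectance_cube(out, cube_corrected$band_centers, method = "wa")
}

#' Max-spectral reflectance estimate
#'
#' Treats the per-band maximum over the scene pixels `X` (everything except
#' the white diffuser and the ColorChecker) as a white point; no `rho_wd`
#' factor is applied. Biased when no near-white object is visible, e.g. on
#' vegetation-only scenes that absorb strongly in the visible domain.
#'
#' @param cube_corrected Vignetting-corrected [radiance_cube()].
#' @param exclude_mask Logical `H x W` mask of pixels EXCLUDED from `X`
#'   (white diffuser and ColorChecker).
#' @return A [reflectance_cube()] tagged `"ms"`.
#' @export
estimate_ms <- function(cube_corrected, exclude_mask) {
  X <- !exclude_mask
  if (!any(X)) stop("X is empty: everything is excluded")
  vals <- cube_corrected$values
  d <- dim(vals)
  out <- array(0, dim = d)
  for (b in seq_len(d[3])) {
    ch <- vals[, , b]
    out[, , b] <- .div_guard(ch, max(ch[X]), "channel maximum")
  }
  reflectance_cube(out, cube_corrected$band_centers, method = "ms")
}

# Row-wise white-diffuser denominators: D[y, b] = median of the m highest
# WD values of row y in band b.
.rw_denominators <- function(vals, wd_mask, m) {
  d <- dim(vals)
  per_row <- rowSums(wd_mask)
  if (any(per_row == 0))
    stop("WD mask must be nonempty in every image row (empty rows: ",
         paste(utils::head(which(per_row == 0), 5), collapse = ", "), ")")
  if (m > min(per_row))
    stop("m exceeds the WD pixel count of some row")
  D <- matrix(0, d[1], d[3])
  for (b in seq_len(d[3])) {
    ch <- vals[, , b]
    for (y in seq_len(d[1]))
      D[y, b] <- .top_m_median(ch[y, wd_mask[y, ]], m)
  }
  D
}

#' Row-wise reflectance estimate (illumination-variation robust)
#'
#' For each image row `y` and band `b`, the illumination level is the
#' median of the `m` highest white-diffuser border values in that row and
#' band; `R_p^b = rho_wd * I_p^b / D_{y_p}^b` for every pixel of the row.
#' Because the numerator and its row's denominator were acquired in the
#' same frame, the estimate cancels the frame-time illumination exactly
#' (up to quantization) even when illumination varies arbitrarily between
#' frames.
#'
#' @param cube_corrected Vignetting-corrected [radiance_cube()].
#' @param wd_mask Logical `H x W` white-diffuser border mask, nonempty in
#'   every row.
#' @param rho_wd White-diffuser reflection factor.
#' @param m Number of top WD values per row entering the median (default 11).
#' @return A [reflectance_cube()] tagged `"rw"`.
#' @export
estimate_rw <- function(cube_corrected, wd_mask, rho_wd = 0.95, m = 11L) {
  vals <- cube_corrected$values
  D <- .rw_denominators(vals, wd_mask, m)
  d <- dim(vals)
  out <- array(0, dim = d)
  for (b in seq_len(d[3]))
    out[, , b] <- rho_wd * .div_guard(vals[, , b], D[, b], "row denominator")
  reflectance_cube(out, cube_corrected$band_centers, method = "rw")
}

#' Double-reference reflectance estimate
#'
#' Adaptation of the two-reference scheme to a linescan acquisition, in
#' three stages: (1) a coarse row-wise reflectance from the WD border (as
#' [estimate_rw()]); (2) a per-band illumination scaling factor relating
#' the time-averaged WD illumination to the illumination seen at the rows
#' of the fully visible second reference (the ColorChecker white patch WP);
#' (3) channel-wise normalization by the mean coarse reflectance over WP,
#' clipped to at most 1 (which can saturate bright near-infrared values).
#'
#' @param cube_corrected Vignetting-corrected [radiance_cube()].
#' @param wd_mask Logical WD border mask (nonempty in every row).
#' @param wp_mask Logical mask of the white-patch second reference.
#' @param rho_wd White-diffuser reflection factor.
#' @param m Top-value count for the row medians.
#' @return A [reflectance_cube()] tagged `"dwd"`, values clipped to <= 1.
#' @export
estimate_dwd <- function(cube_corrected, wd_mask, wp_mask, rho_wd = 0.95,
                         m = 11L) {
  if (!any(wp_mask)) stop("WP mask is empty")
  vals <- cube_corrected$values
  d <- dim(vals)
  D <- .rw_denominators(vals, wd_mask, m)
  wp_rows <- which(rowSums(wp_mask) > 0)
  coarse <- array(0, dim = d)
  for (b in seq_len(d[3]))
    coarse[, , b] <- rho_wd * .div_guard(vals[, , b], D[, b],
                                         "row denominator")
  out <- array(0, dim = d)
  for (b in seq_len(d[3])) {
    f_b <- mean(D[, b]) / mean(D[wp_rows, b])   # illumination scaling
    ch <- coarse[, , b]
    norm_b <- mean(ch[wp_mask])                 # WP normalization
    out[, , b] <- pmin(.div_guard(f_b * ch, norm_b, "WP mean"), 1)
  }
  reflectance_cube(out, cube_corrected$band_centers, method = "dwd")
}

#' Fit a Wiener reflectance-estimation transform
#'
#' Learns the linear least-squares map from radiance to reflectance on
#' reference patch spectra: with columns centered by their mean spectra,
#' `G = Tref Trad' (Trad Trad')^+`. For `K` bands and `n < K` training
#' patches the `K x K` Gram matrix is rank deficient, so the inverse is
#' realized as the Moore-Penrose pseudo-inverse (the unique minimum-norm
#' solution).
#'
#' @param ref_spectra `K x n` matrix of reference patch reflectance spectra
#'   (one column per patch).
#' @param rad_spectra `K x n` matrix of the corresponding radiance spectra.
#' @return Object of class `wiener_model` with `G`, `mean_rad`, `mean_ref`.
#' @export
wiener_fit <- function(ref_spectra, rad_spectra) {
  ref_spectra <- as.matrix(ref_spectra); rad_spectra <- as.matrix(rad_spectra)
  if (!identical(dim(ref_spectra), dim(rad_spectra)))
    stop("ref and rad spectra must share dimensions")
  if (ncol(ref_spectra) < 2L) stop("need at least 2 training spectra")
  mean_ref <- rowMeans(ref_spectra)
  mean_rad <- rowMeans(rad_spectra)
  Tref <- ref_spectra - mean_ref
  Trad <- rad_spectra - mean_rad
  G <- Tref %*% t(Trad) %*% MASS::ginv(Trad %*% t(Trad))
  structure(list(G = G, mean_rad = mean_rad, mean_ref = mean_ref),
            class = "wiener_model")
}

#' Apply a Wiener transform to a radiance cube
#'
#' Default affine form `R_p = G (I_p - mean_rad) + mean_ref`, consistent
#' with the centered fit; `affine = FALSE` applies the bare linear map
#' `G I_p` on uncentered radiance.
#'
#' @param model A `wiener_model`.
#' @param cube_corrected Spectrally corrected, vignetting-corrected
#'   [radiance_cube()] with `K` channels matching the model.
#' @param affine Logical, default `TRUE`.
#' @return A [reflectance_cube()] tagged `"wn"`.
#' @export
wiener_apply <- function(model, cube_corrected, affine = TRUE) {
  vals <- cube_corrected$values
  d <- dim(vals)
  if (d[3] != nrow(model$G))
    stop("cube channel count does not match the Wiener model")
  X <- matrix(vals, d[1] * d[2], d[3])
  Y <- if (affine)
    sweep(X, 2, model$mean_rad) %*% t(model$G) +
      matrix(model$mean_ref, d[1] * d[2], d[3], byrow = TRUE)
  else X %*% t(model$G)
  reflectance_cube(array(Y, dim = d), cube_corrected$band_centers,
                   method = "wn", spectrally_corrected = TRUE)
}

#' Apply the sparse spectral-correction matrix
#'
#' Maps the `B` raw sensor bands onto `K` "virtual" bands, `out = M in` per
#' pixel, replacing the band centers; the working spectral domain is
#' unchanged. Because `M` can carry negative coefficients, negative outputs
#' are possible (see [remove_negatives()]).
#'
#' @param cube A `B`-channel [radiance_cube()] or [reflectance_cube()].
#' @param cm A [correction_matrix()].
#' @return A cube of the same class with `K` channels.
#' @export
spectral_correct <- function(cube, cm) {
  vals <- cube$values
  d <- dim(vals)
  if (d[3] != ncol(cm$M))
    stop("cube has ", d[3], " channels but the correction matrix expects ",
         ncol(cm$M))
  X <- matrix(vals, d[1] * d[2], d[3])
  Y <- X %*% t(cm$M)
  out <- array(Y, dim = c(d[1], d[2], nrow(cm$M)))
  if (inherits(cube, "reflectance_cube"))
    reflectance_cube(out, cm$out_band_centers, method = cube$method,
                     spectrally_corrected = TRUE,
                     negatives_removed = cube$negatives_removed)
  else
    radiance_cube(out, cm$out_band_centers, tau = cube$tau,
                  quantized = FALSE, bit_depth = cube$bit_depth)
}

#' Remove negative reflectance values by conditional median filtering
#'
#' Negative values (from dark-frame subtraction and the signed correction
#' matrix) carry no physical meaning. Each negative pixel is replaced, per
#' channel, by the 3 x 3 median of the ORIGINAL channel (single pass, no
#' sequential propagation; reflect padding at borders); non-negative pixels
#' are untouched. A fully negative neighborhood stays negative; the count
#' of such remaining negatives is reported with a warning.
#'
#' @param cube A [reflectance_cube()].
#' @return The filtered [reflectance_cube()] with `negatives_removed = TRUE`.
#' @export
remove_negatives <- function(cube) {
  vals <- cube$values
  d <- dim(vals)
  out <- vals
  for (b in seq_len(d[3])) {
    ch <- vals[, , b]
    neg <- ch < 0
    if (!any(neg)) next
    med <- .median3(ch)
    ch[neg] <- med[neg]
    out[, , b] <- ch
  }
  remaining <- sum(out < 0)
  if (remaining > 0)
    warning(remaining,
            " negative value(s) remain after median replacement",
            " (fully negative neighborhoods)")
  reflectance_cube(out, cube$band_centers, method = cube$method,
                   spectrally_corrected = cube$spectrally_corrected,
                   negatives_removed = TRUE)
}
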