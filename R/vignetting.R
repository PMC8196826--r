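# Flat-field vignetting correction. The lens attenuates radiance toward the
# image borders; a full-field white-diffuser cube acquired once under
# controlled constant illumination exposes that fall-off, from which
# per-pixel, per-band multiplicative correction factors are estimated.

#' Estimate raw vignetting correction factors from a white cube
#'
#' For each band `b`, the reference level `I_b` is the median of the `m`
#' highest pixel values of the channel (discarding saturated or defective
#' pixels); the factor at pixel `p` is `C_p^b = I_b / I_p^b`.
#'
#' @param white_cube Full-field white-diffuser [radiance_cube()], strictly
#'   positive.
#' @param m Number of top values entering the reference median (default 11;
#'   for even `m` the lower median is taken).
#' @return Object of class `vignetting_model` with raw factors `C`
#'   (`H x W x B`), `m`, and `smoothed = FALSE`.
#' @export
correction_factors <- function(white_cube, m = 11L) {
  vals <- white_cube$values
  d <- dim(vals)
  if (m > d[1] * d[2]) stop("m exceeds the per-channel pixel count")
  zero <- which(vals <= 0, arr.ind = TRUE)
  if (nrow(zero) > 0)
    stop("white cube has non-positive pixels at ",
         paste(utils::head(apply(zero, 1, paste, collapse = ","), 5),
               collapse = "; "),
         if (nrow(zero) > 5) " ..." else "")
  C <- array(0, dim = d)
  for (b in seq_len(d[3])) {
    ch <- vals[, , b]
    C[, , b] <- .top_m_median(as.vector(ch), m) / ch
  }
  structure(list(C = C, m = as.integer(m), smoothed = FALSE),
            class = "vignetting_model")
}

#' Smooth vignetting factors with an 11 x 11 averaging filter
#'
#' Denoises the raw factor image (estimated from a single white cube)
#' channel-wise with a uniform mean filter; borders use reflect padding.
#'
#' @param model A `vignetting_model` with raw factors.
#' @param k Filter side length (odd; default 11).
#' @return The model with `C_smooth` added and `smoothed = TRUE`.
#' @export
smooth_factors <- function(model, k = 11L) {
  d <- dim(model$C)
  Cs <- array(0, dim = d)
  for (b in seq_len(d[3])) Cs[, , b] <- .box_filter(model$C[, , b], k)
  model$C_smooth <- Cs
  model$smoothed <- TRUE
  model
}

#' Apply vignetting correction to a radiance cube
#'
#' Multiplies the cube channel-wise and pixel-wise by the correction
#' factors (smoothed factors when present). After correction the residual
#' attenuation is spatially uniform per band, which is what the downstream
#' single-reference estimators assume.
#'
#' @param cube A [radiance_cube()].
#' @param model A `vignetting_model`.
#' @param use_smoothed Use `C_smooth` when available (default `TRUE`).
#' @return A floating-valued corrected [radiance_cube()].
#' @export
apply_correction <- function(cube, model, use_smoothed = TRUE) {
  fac <- if (use_smoothed && !is.null(model$C_smooth)) model$C_smooth
         else model$C
  if (!identical(dim(cube$values), dim(fac)))
    stop("cube and vignetting model shapes differ")
  radiance_cube(cube$values * fac, cube$band_centers, tau = cube$tau,
                quantized = FALSE, bit_depth = cube$bit_depth)
}
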