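#' Sensor configuration for a multishot linescan camera
#'
#' Describes the filter-striped sensor and acquisition parameters. The sensor
#' carries `B` narrow-band Fabry-Perot filters, each covering `v` adjacent
#' pixel rows (a filter stripe); between two successive frames the sensor
#' moves by exactly `v` rows, so every pixel/band pair of the assembled cube
#' is measured at its own frame time.
#'
#' @param B Number of optical filters (spectral bands). Default 192.
#' @param v Rows per filter stripe, in pixels; also the inter-frame step.
#'   Default 5.
#' @param W Sensor width in pixels. Default 2048.
#' @param band_centers Strictly increasing filter central wavelengths (nm),
#'   length `B`. Default: evenly spaced over the working domain.
#' @param ssf_model Spectral sensitivity model, `"dirac"` (ideal
#'   single-wavelength sampling) or `"gaussian"` (FWHM-parameterised band).
#' @param fwhm Full width at half maximum per band (nm); scalar or length-`B`.
#' @param y0 Sensor row offset in camera coordinates at the first frame.
#' @param frame_period Frame acquisition period (abstract time units); fixed
#'   at 1, illumination is indexed per frame.
#' @param bit_depth Quantization depth of the analog-to-digital converter.
#' @param rho_wd Diffuse reflection factor of the white diffuser reference,
#'   dimensionless in (0, 1]. Default 0.95.
#' @param omega Working wavelength domain (nm), closed interval of length 2.
#'
#' @return An object of class `sensor_config`.
#' @export
sensor_config <- function(B = 192L, v = 5L, W = 2048L,
                          band_centers = NULL,
                          ssf_model = c("dirac", "gaussian"),
                          fwhm = 6,
                          y0 = 0,
                          frame_period = 1,
                          bit_depth = 10L,
                          rho_wd = 0.95,
                          omega = c(475.1, 901.7)) {
  ssf_model <- match.arg(ssf_model)
  B <- as.integer(B); v <- as.integer(v); W <- as.integer(W)
  bit_depth <- as.integer(bit_depth)
  if (B < 1L) stop("B must be >= 1")
  if (v < 1L) stop("v must be >= 1")
  if (bit_depth < 1L) stop("bit_depth must be >= 1")
  if (!(rho_wd > 0 && rho_wd <= 1)) stop("rho_wd must be in (0, 1]")
  if (length(omega) != 2L || omega[1] >= omega[2])
    stop("omega must be an increasing interval c(min, max)")
  if (is.null(band_centers)) {
    band_centers <- if (B == 1L) mean(omega) else
      seq(omega[1], omega[2], length.out = B)
  }
  if (length(band_centers) != B)
    stop("band_centers must have length B")
  if (B > 1L && any(diff(band_centers) <= 0))
    stop("band_centers must be strictly increasing")
  if (any(band_centers < omega[1] - 1e-9 | band_centers > omega[2] + 1e-9))
    stop("band_centers must lie inside omega")
  fwhm <- rep_len(as.numeric(fwhm), B)
  if (any(fwhm <= 0)) stop("fwhm must be positive")
  structure(list(B = B, v = v, W = W,
                 band_centers = as.numeric(band_centers),
                 ssf_model = ssf_model, fwhm = fwhm,
                 y0 = as.numeric(y0), frame_period = frame_period,
                 bit_depth = bit_depth, rho_wd = rho_wd,
                 omega = as.numeric(omega)),
            class = "sensor_config")
}

#' @export
print.sensor_config <- function(x, ...) {
  cat(sprintf("<sensor_config> B=%d bands (%.1f-%.1f nm), stripe v=%d px, W=%d px\n",
              x$B, min(x$band_centers), max(x$band_centers), x$v, x$W))
  cat(sprintf("  ssf=%s, bit_depth=%d, rho_wd=%.2f\n",
              x$ssf_model, x$bit_depth, x$rho_wd))
  invisible(x)
}

# Maximum representable count of the quantizer.
.max_count <- function(config) 2^config$bit_depth - 1

# Spectral-sensitivity weight matrix: row b holds the discrete quadrature
# weights of filter b on the band-center wavelength grid, normalized to unit
# sum. Dirac SSF reduces to the identity (single-term sampling); the gaussian
# SSF uses trapezoidal weights on the grid, renormalized.
.ssf_weights <- function(config) {
  B <- config$B
  if (config$ssf_model == "dirac" || B == 1L) return(diag(B))
  lam <- config$band_centers
  d <- diff(lam)
  trap <- c(d[1] / 2, (d[-1] + d[-length(d)]) / 2, d[length(d)] / 2)
  sigma <- config$fwhm / (2 * sqrt(2 * log(2)))
  Wm <- matrix(0, B, B)
  for (b in seq_len(B)) {
    w <- trap * exp(-(lam - lam[b])^2 / (2 * sigma[b]^2))
    Wm[b, ] <- w / sum(w)
  }
  Wm
}
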