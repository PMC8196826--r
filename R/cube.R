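#' Radiance cube container
#'
#' A spectral radiance image stored as an `H x W x C` numeric array (axis
#' order row, column, band) with band metadata. Raw cubes carry `C = B`
#' sensor bands; spectrally corrected cubes carry `C = K` virtual bands.
#' Quantized cubes hold integers; negative values are legal after dark-frame
#' subtraction.
#'
#' @param values `H x W x C` numeric array.
#' @param band_centers Length-`C` band central wavelengths (nm).
#' @param tau Integration time used during acquisition (abstract units).
#' @param quantized Logical; `TRUE` when values are quantized counts.
#' @param bit_depth Quantizer depth, required to validate quantized payloads.
#' @return An object of class `radiance_cube`.
#' @export
radiance_cube <- function(values, band_centers, tau = 1, quantized = FALSE,
                          bit_depth = 10L) {
  if (length(dim(values)) != 3L)
    stop("values must be a 3-d array (row, column, band)")
  if (dim(values)[3] != length(band_centers))
    stop("band_centers length must equal the number of channels")
  if (quantized) {
    lim <- 2^bit_depth - 1
    if (any(values != round(values)))
      stop("quantized cube must hold integer counts")
    if (any(values > lim) || any(values < -lim))
      stop("quantized counts out of the representable range")
  }
  structure(list(values = values,
                 band_centers = as.numeric(band_centers),
                 tau = tau, quantized = quantized,
                 bit_depth = as.integer(bit_depth)),
            class = "radiance_cube")
}

#' Reflectance cube container
#'
#' Per-pixel spectral reflectance estimates produced by one of the
#' estimators (`ref`, `wa`, `ms`, `rw`, `dwd`, `wn`).
#'
#' @param values `H x W x C` array of reflectance estimates.
#' @param band_centers Length-`C` wavelengths (nm).
#' @param method Estimator tag.
#' @param spectrally_corrected Logical; `TRUE` after the K-band correction.
#' @param negatives_removed Logical; `TRUE` after conditional median filtering.
#' @return An object of class `reflectance_cube`.
#' @export
reflectance_cube <- function(values, band_centers,
                             method = c("ref", "wa", "ms", "rw", "dwd", "wn"),
                             spectrally_corrected = FALSE,
                             negatives_removed = FALSE) {
  method <- match.arg(method)
  if (length(dim(values)) != 3L)
    stop("values must be a 3-d array (row, column, band)")
  if (dim(values)[3] != length(band_centers))
    stop("band_centers length must equal the number of channels")
  structure(list(values = values,
                 band_centers = as.numeric(band_centers),
                 method = method,
                 spectrally_corrected = spectrally_corrected,
                 negatives_removed = negatives_removed),
            class = "reflectance_cube")
}

#' @export
print.radiance_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<radiance_cube> %d x %d px, %d bands (%.1f-%.1f nm), tau=%g%s\n",
              d[1], d[2], d[3], min(x$band_centers), max(x$band_centers),
              x$tau, if (x$quantized) ", quantized" else ""))
  invisible(x)
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<reflectance_cube> %d x %d px, %d bands, method=%s%s%s\n",
              d[1], d[2], d[3], x$method,
              if (x$spectrally_corrected) ", spectrally corrected" else "",
              if (x$negatives_removed) ", negatives removed" else ""))
  invisible(x)
}

#' Region masks attached to an acquisition
#'
#' Boolean masks for the in-scene reference devices and integer label maps.
#' `wd` marks the white-diffuser border band along the right image edge
#' (spans all rows), `ws` a small white square sampled inside it, `wp` the
#' ColorChecker white patch. `patches` labels ColorChecker patches (0 =
#' none), `classes` labels vegetation classes (0 = background).
#'
#' @param wd,ws,wp Logical `H x W` matrices (may be all-`FALSE`).
#' @param patches,classes Integer `H x W` label matrices.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(wd, ws = NULL, wp = NULL, patches = NULL, classes = NULL) {
  dm <- dim(wd)
  blank <- function(x, mode) {
    if (is.null(x)) return(array(vector(mode, 1L), dm))
    if (!identical(dim(x), dm)) stop("all masks must share the cube's H x W")
    x
  }
  ws <- blank(ws, "logical"); wp <- blank(wp, "logical")
  patches <- blank(patches, "integer"); classes <- blank(classes, "integer")
  if (any(ws & !wd)) stop("ws must be a subset of wd")
  structure(list(wd = wd, ws = ws, wp = wp,
                 patches = patches, classes = classes),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> %d x %d px: |WD|=%d, |WS|=%d, |WP|=%d, %d patches, %d classes\n",
              nrow(x$wd), ncol(x$wd), sum(x$wd), sum(x$ws), sum(x$wp),
              length(setdiff(unique(as.vector(x$patches)), 0L)),
              length(setdiff(unique(as.vector(x$classes)), 0L))))
  invisible(x)
}
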