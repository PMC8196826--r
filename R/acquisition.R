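# Image-formation model for a multishot linescan camera. The filter-striped
# sensor advances by one stripe (v rows) between frames, so channel b of
# stripe-block j of the assembled cube is measured in the frame acquired at
# t = (n_blocks - 1 - j) + b: for a given channel, the TOP image rows are
# acquired LATER (a consequence of the stacking order of stripe assembly,
# fixed here as the package's convention). Band indices b, block indices j
# and frame times t are all 0-based, matching the formation-model algebra;
# array accessors remain 1-based as usual in R.

#' Filter index observed at a camera-coordinate row
#'
#' At frame time `t`, the sensor row at camera coordinate `y` sits under the
#' filter of index `b = t + (y - y0)/v` (0-based).
#'
#' @param t Frame time index (0-based).
#' @param y Camera-coordinate row of the observed point.
#' @param y0 Sensor row offset at `t = 0`.
#' @param v Stripe height in pixels.
#' @param B Filter count; when finite, out-of-range results raise an error.
#' @return The 0-based filter index.
#' @export
filter_index <- function(t, y, y0, v, B = Inf) {
  if ((y - y0) %% v != 0)
    stop("(y - y0) must be a multiple of v under the row-block convention")
  b <- t + (y - y0) / v
  if (any(b < 0) || any(b >= B))
    stop("filter index out of range [0, B)")
  b
}

#' Acquisition-time map of an assembled cube
#'
#' @param h Assembled image height in pixels (multiple of `config$v`).
#' @param config A [sensor_config()].
#' @return Object of class `time_map` with `t(b, j)` (0-based band and
#'   stripe-block indices to 0-based frame time), `n_blocks = h/v` and
#'   `n_frames = h/v + B - 1`.
#' @export
time_map <- function(h, config) {
  if (h %% config$v != 0) stop("h must be a multiple of the stripe height v")
  n_blocks <- as.integer(h / config$v)
  B <- config$B
  n_frames <- n_blocks + B - 1L
  tfun <- function(b, j) {
    if (any(b < 0) || any(b >= B)) stop("band index out of range [0, B)")
    if (any(j < 0) || any(j >= n_blocks)) stop("block index out of range")
    (n_blocks - 1L - j) + b
  }
  structure(list(t = tfun, n_blocks = n_blocks, n_frames = n_frames,
                 v = config$v, B = B),
            class = "time_map")
}

#' Dark-signal model
#'
#' @param offset Mean dark level in counts (>= 0).
#' @param read_noise_sd Read-noise standard deviation in counts (>= 0).
#' @param seed Integer seed for the noise draws.
#' @return Object of class `dark_model`.
#' @export
dark_model <- function(offset = 0, read_noise_sd = 0, seed = 1L) {
  if (offset < 0) stop("offset must be >= 0")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  structure(list(offset = offset, read_noise_sd = read_noise_sd,
                 seed = as.integer(seed)),
            class = "dark_model")
}

# Round-half-to-even quantizer with clipping to the representable range.
.quantize <- function(x, bit_depth) .clamp(round(x), 0, 2^bit_depth - 1)

# Read-noise field for frame t (or the dark exposure for t = -1), seeded so
# that the frame pipeline and the direct simulator draw identical values.
.noise_field <- function(dark, t, nr, nc) {
  if (dark$read_noise_sd == 0) return(matrix(0, nr, nc))
  set.seed(dark$seed + t + 1L)
  matrix(stats::rnorm(nr * nc, 0, dark$read_noise_sd), nr, nc)
}

# Unquantized stripe signal: tau * sum_l w_bl E_t(l) R(l) A(l) for the v
# scene rows of block j (0-based) under filter b (0-based).
.stripe_signal <- function(RA_flat, rows_idx, Evec, wrow, tau, v, W) {
  X <- RA_flat[rows_idx, , drop = FALSE]       # (v*W) x B
  matrix(tau * (X %*% (wrow * Evec)), v, W)
}

# Flatten reflectance*attenuation to (H*W) x B once; rows of block j (0-based)
# map to flat indices for rows j*v + 1 .. j*v + v across all columns.
.flatten_RA <- function(scene, atten) {
  d <- dim(scene$reflectance)
  A <- if (is.null(atten)) 1 else atten$A
  matrix(scene$reflectance * A, d[1] * d[2], d[3])
}
.block_flat_idx <- function(j, v, h, W) {
  rows <- j * v + seq_len(v)
  as.vector(outer(rows, (seq_len(W) - 1L) * h, "+"))
}

#' Simulate the frame sequence of a linescan acquisition
#'
#' Each frame is a `(B v) x W` exposure: frame row `r` (0-based) lies under
#' filter `b = floor(r/v)`; its unquantized value is
#' `tau * sum_l w_bl E_t(lambda_l) R(lambda_l) A(lambda_l)` on the
#' band-center grid (Dirac SSF: a single term; Gaussian SSF: normalized
#' trapezoidal quadrature). The dark offset and per-frame read noise are
#' added, the result quantized (round-half-to-even, clipped to the bit
#' depth), and a single independently sampled quantized dark frame is
#' subtracted — so small negative counts can appear, as on the real camera.
#'
#' @param scene A [scene_truth()].
#' @param illum An [make_illumination()] series covering all frame times.
#' @param atten An [make_attenuation()] field, or `NULL` for no attenuation.
#' @param config A [sensor_config()].
#' @param tau Integration time (> 0).
#' @param dark A [dark_model()].
#' @return A list of frames (`values`, `t`) with attributes `tau`, `h`,
#'   `n_saturated` (count of clipped pixels over all frames).
#' @export
acquire_frames <- function(scene, illum, atten, config, tau,
                           dark = dark_model()) {
  if (tau <= 0) stop("tau must be > 0")
  d <- dim(scene$reflectance)
  h <- d[1]; W <- d[2]
  tm <- time_map(h, config)
  if (nrow(illum$E) < tm$n_frames)
    stop("illumination series shorter than the acquisition (need ",
         tm$n_frames, " frames)")
  B <- config$B; v <- config$v
  Wm <- .ssf_weights(config)
  RA <- .flatten_RA(scene, atten)
  maxc <- .max_count(config)
  dark_q <- .quantize(dark$offset + .noise_field(dark, -1L, B * v, W),
                      config$bit_depth)
  n_sat <- 0L
  frames <- vector("list", tm$n_frames)
  for (t in 0:(tm$n_frames - 1L)) {
    f <- matrix(0, B * v, W)
    Evec_t <- illum$E[t + 1L, ]
    for (b in 0:(B - 1L)) {
      j <- tm$n_blocks - 1L - t + b
      if (j < 0L || j >= tm$n_blocks) next
      idx <- .block_flat_idx(j, v, h, W)
      f[b * v + seq_len(v), ] <-
        .stripe_signal(RA, idx, Evec_t, Wm[b + 1L, ], tau, v, W)
    }
    pre <- f + dark$offset + .noise_field(dark, t, B * v, W)
    n_sat <- n_sat + sum(round(pre) > maxc)
    frames[[t + 1L]] <- list(values = .quantize(pre, config$bit_depth) - dark_q,
                             t = t)
  }
  attr(frames, "tau") <- tau
  attr(frames, "h") <- h
  attr(frames, "n_saturated") <- n_sat
  frames
}

#' Assemble a frame sequence into a multispectral radiance cube
#'
#' Channel `b`, stripe-block `j` of the cube is stripe `b` of the frame
#' acquired at `t(b, j)`; the output height is `n_blocks * v`.
#'
#' @param frames Output of [acquire_frames()].
#' @param config A [sensor_config()].
#' @return A quantized [radiance_cube()].
#' @export
assemble <- function(frames, config) {
  h <- attr(frames, "h")
  if (is.null(h))
    stop("frames lack acquisition metadata; pass the list from acquire_frames")
  tm <- time_map(h, config)
  if (length(frames) != tm$n_frames)
    stop("expected ", tm$n_frames, " frames, got ", length(frames))
  B <- config$B; v <- config$v
  W <- ncol(frames[[1]]$values)
  vals <- array(0, dim = c(h, W, B))
  for (b in 0:(B - 1L)) for (j in 0:(tm$n_blocks - 1L)) {
    t <- tm$t(b, j)
    vals[j * v + seq_len(v), , b + 1L] <-
      frames[[t + 1L]]$values[b * v + seq_len(v), ]
  }
  cube <- radiance_cube(vals, config$band_centers, tau = attr(frames, "tau"),
                        quantized = TRUE, bit_depth = config$bit_depth)
  attr(cube, "n_saturated") <- attr(frames, "n_saturated")
  cube
}

#' Simulate an assembled cube directly from the acquisition-time map
#'
#' Computes each cube value `I_p^b` from the formation model without
#' materialising frames, drawing identical noise fields, and therefore
#' serves as the independent oracle for the frame pipeline
#' ([acquire_frames()] + [assemble()]), with which it agrees bit-exactly.
#'
#' @inheritParams acquire_frames
#' @param quantize Logical; set `FALSE` to return the unquantized noise-free
#'   signal (used for exposure search).
#' @return A [radiance_cube()] (quantized unless `quantize = FALSE`).
#' @export
simulate_direct <- function(scene, illum, atten, config, tau,
                            dark = dark_model(), quantize = TRUE) {
  if (tau <= 0) stop("tau must be > 0")
  d <- dim(scene$reflectance)
  h <- d[1]; W <- d[2]
  tm <- time_map(h, config)
  if (nrow(illum$E) < tm$n_frames)
    stop("illumination series shorter than the acquisition (need ",
         tm$n_frames, " frames)")
  B <- config$B; v <- config$v
  Wm <- .ssf_weights(config)
  RA <- .flatten_RA(scene, atten)
  maxc <- .max_count(config)
  vals <- array(0, dim = c(h, W, B))
  if (quantize) {
    dark_q <- .quantize(dark$offset + .noise_field(dark, -1L, B * v, W),
                        config$bit_depth)
    noise_cache <- new.env(parent = emptyenv())
    get_noise <- function(t) {
      key <- as.character(t)
      if (!exists(key, envir = noise_cache, inherits = FALSE))
        assign(key, .noise_field(dark, t, B * v, W), envir = noise_cache)
      get(key, envir = noise_cache, inherits = FALSE)
    }
  }
  n_sat <- 0L
  for (b in 0:(B - 1L)) for (j in 0:(tm$n_blocks - 1L)) {
    t <- tm$t(b, j)
    idx <- .block_flat_idx(j, v, h, W)
    sig <- .stripe_signal(RA, idx, illum$E[t + 1L, ], Wm[b + 1L, ], tau, v, W)
    if (quantize) {
      stripe <- b * v + seq_len(v)
      pre <- sig + dark$offset + get_noise(t)[stripe, , drop = FALSE]
      n_sat <- n_sat + sum(round(pre) > maxc)
      sig <- .quantize(pre, config$bit_depth) - dark_q[stripe, , drop = FALSE]
    }
    vals[j * v + seq_len(v), , b + 1L] <- sig
  }
  cube <- radiance_cube(vals, config$band_centers, tau = tau,
                        quantized = quantize, bit_depth = config$bit_depth)
  attr(cube, "n_saturated") <- n_sat
  cube
}

#' Largest integration time that avoids saturation
#'
#' Exploits the linearity of the unquantized formation model: the returned
#' `tau` scales the noise-free signal maximum (plus dark offset) exactly to
#' the top of the quantizer range.
#'
#' @inheritParams acquire_frames
#' @return The exposure time `tau`.
#' @export
auto_exposure <- function(scene, illum, atten, config, dark = dark_model()) {
  base <- simulate_direct(scene, illum, atten, config, tau = 1,
                          dark = dark, quantize = FALSE)
  mx <- max(base$values)
  if (mx <= 0) stop("all-zero radiance: cannot set exposure")
  (.max_count(config) - dark$offset) / mx
}
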