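# Small numeric helpers shared across modules.

# Reflect-pad a matrix by k rows/columns on each side (edge row/col mirrored
# without repeating the border pixel's neighbour order: "reflect" in the
# scipy sense, i.e. abcd -> b a | a b c d | d c).
.reflect_pad <- function(mat, k) {
  n <- nrow(mat); m <- ncol(mat)
  if (k > n || k > m) stop("pad width exceeds image size")
  ri <- c(rev(seq_len(k)), seq_len(n), n + 1 - seq_len(k))
  ci <- c(rev(seq_len(k)), seq_len(m), m + 1 - seq_len(k))
  mat[ri, ci, drop = FALSE]
}

# k x k uniform mean filter with reflect padding, computed exactly with
# separable running sums (no FFT round-off).
.box_filter <- function(mat, k) {
  if (k %% 2 != 1) stop("box filter size must be odd")
  half <- (k - 1) / 2
  if (half == 0) return(mat)
  p <- .reflect_pad(mat, half)
  run <- function(m) {
    # column-wise running sum of k consecutive rows
    cs <- apply(m, 2, cumsum)
    if (!is.matrix(cs)) cs <- matrix(cs, ncol = ncol(m))
    top <- rbind(matrix(0, 1, ncol(m)), cs)
    cs[k:nrow(m), , drop = FALSE] - top[1:(nrow(m) - k + 1), , drop = FALSE]
  }
  s <- run(p)             # (H x (W+2h)) sums over rows
  s <- t(run(t(s)))       # H x W sums over rows and cols
  s / (k * k)
}

# 3x3 median filter with reflect padding, evaluated on the ORIGINAL image
# (single pass). Returns the full filtered matrix.
.median3 <- function(mat) {
  p <- .reflect_pad(mat, 1L)
  n <- nrow(mat); m <- ncol(mat)
  stack <- array(NA_real_, dim = c(n, m, 9L))
  idx <- 1L
  for (dr in 0:2) for (dc in 0:2) {
    stack[, , idx] <- p[dr + seq_len(n), dc + seq_len(m)]
    idx <- idx + 1L
  }
  apply(stack, c(1, 2), stats::median)
}

# Median of the m highest values of x; for even m the lower median is taken.
# Ties among equal values are immaterial to the result; conceptually the
# first m in row-major pixel order are retained.
.top_m_median <- function(x, m) {
  if (m > length(x)) stop("m exceeds the number of available values")
  top <- sort(x, decreasing = TRUE)[seq_len(m)]
  sort(top)[floor((m + 1) / 2)]
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
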