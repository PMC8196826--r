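# ENVI-style cube persistence: a flat binary file in band-sequential (BSQ)
# order next to a plain-text header "<file>.hdr". Only the subset of the
# header dialect needed for these cubes is supported (samples/lines/bands,
# data type, interleave, byte order, wavelength list).

.envi_dtype <- function(code) {
  switch(as.character(code),
         "2"  = list(what = "integer", size = 2L, signed = TRUE),
         "4"  = list(what = "numeric", size = 4L, signed = TRUE),
         "5"  = list(what = "numeric", size = 8L, signed = TRUE),
         "12" = list(what = "integer", size = 2L, signed = FALSE),
         stop("unsupported ENVI data type code: ", code))
}

.header_path <- function(path) {
  if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
}
.binary_path <- function(path) sub("\\.hdr$", "", path)

#' Write a spectral cube to an ENVI-style file pair
#'
#' The binary payload is written at `path` in BSQ interleave, little endian,
#' with the header at `path.hdr`. Quantized cubes are stored as 16-bit
#' integers (signed when negatives are present, as after dark-frame
#' subtraction; unsigned otherwise); floating cubes as 64-bit IEEE doubles,
#' so that a read/write cycle is bit-exact.
#'
#' @param cube A [radiance_cube()] or [reflectance_cube()].
#' @param path Output path of the binary file (e.g. `"cube.bsq"`).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  vals <- cube$values
  d <- dim(vals)
  quantized <- isTRUE(cube$quantized)
  dtype <- if (quantized) {
    if (min(vals) < 0) 2L else 12L
  } else 5L
  info <- .envi_dtype(dtype)
  con <- tryCatch(file(.binary_path(path), "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con), add = TRUE)
  # BSQ: per band, lines (rows) of samples in row-major order
  for (b in seq_len(d[3])) {
    v <- as.vector(t(vals[, , b, drop = TRUE]))
    if (info$what == "integer")
      writeBin(as.integer(v), con, size = info$size, endian = "little")
    else
      writeBin(as.numeric(v), con, size = info$size, endian = "little")
  }
  hdr <- c("ENVI",
           "file type = ENVI Standard",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           sprintf("data type = %d", dtype),
           "interleave = bsq",
           "byte order = 0",
           sprintf("tau = %.17g", if (is.null(cube$tau)) 1 else cube$tau),
           sprintf("bit depth = %d",
                   if (is.null(cube$bit_depth)) 10L else cube$bit_depth),
           sprintf("wavelength = {%s}",
                   paste(sprintf("%.17g", cube$band_centers), collapse = ", ")))
  writeLines(hdr, .header_path(path))
  invisible(path)
}

.parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  out <- list()
  pat <- "(?m)^\\s*([a-zA-Z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) stop("malformed ENVI header: ", hdr_path)
  starts <- m; lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    kv <- substr(txt, starts[i], starts[i] + lens[i] - 1)
    key <- trimws(sub("=.*", "", kv))
    val <- trimws(sub("^[^=]*=", "", kv))
    out[[tolower(key)]] <- val
  }
  out
}

#' Read a spectral cube from an ENVI-style file pair
#'
#' @param path Path to the binary file or to its `.hdr` header.
#' @return A [radiance_cube()]; `quantized` is set for integer payloads.
#' @export
read_cube <- function(path) {
  hdr_path <- .header_path(path)
  bin_path <- .binary_path(path)
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path)
  if (!file.exists(bin_path)) stop("missing ENVI binary: ", bin_path)
  h <- .parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type")
  miss <- need[!need %in% names(h)]
  if (length(miss)) stop("ENVI header lacks fields: ", paste(miss, collapse = ", "))
  W <- as.integer(h$samples); H <- as.integer(h$lines); B <- as.integer(h$bands)
  if (!is.null(h$interleave) && tolower(h$interleave) != "bsq")
    stop("only BSQ interleave is supported")
  if (is.null(h$wavelength))
    stop("ENVI header lacks a wavelength list")
  wl <- as.numeric(strsplit(gsub("[{}]", "", h$wavelength), ",")[[1]])
  if (length(wl) != B) stop("wavelength list length does not match bands")
  info <- .envi_dtype(as.integer(h$`data type`))
  n <- as.numeric(H) * W * B
  expected <- n * info$size
  if (file.size(bin_path) != expected)
    stop(sprintf("binary size mismatch: %d bytes found, %d expected",
                 file.size(bin_path), expected))
  con <- file(bin_path, "rb")
  on.exit(close(con), add = TRUE)
  raw <- readBin(con, what = info$what, n = n, size = info$size,
                 signed = info$signed, endian = "little")
  vals <- array(if (info$what == "integer") 0L else 0, dim = c(H, W, B))
  per <- H * W
  for (b in seq_len(B))
    vals[, , b] <- t(matrix(raw[((b - 1) * per + 1):(b * per)], nrow = W))
  tau <- if (is.null(h$tau)) 1 else as.numeric(h$tau)
  bd <- if (is.null(h$`bit depth`)) 15L else as.integer(h$`bit depth`)
  radiance_cube(vals, wl, tau = tau,
                quantized = info$what == "integer",
                bit_depth = bd)
}

#' Write an integer label map as a single-band ENVI cube
#'
#' @param labels Integer `H x W` matrix (logical matrices are coerced 0/1).
#' @param path Output binary path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  lab <- array(as.integer(labels), dim = c(dim(labels), 1L))
  write_cube(radiance_cube(lab, band_centers = 0, quantized = TRUE,
                           bit_depth = 15L), path)
}

#' Read an integer label map written by [write_label_map()]
#' @param path Path to the binary or header file.
#' @return Integer `H x W` matrix.
#' @export
read_label_map <- function(path) {
  cube <- read_cube(path)
  matrix(as.integer(cube$values[, , 1]), nrow = dim(cube$values)[1])
}

#' Load a spectral-correction matrix from delimited text
#'
#' Format: first row holds the `K` output ("virtual") band centers (nm);
#' each of the remaining `K` rows holds the `B` coefficients mapping the raw
#' sensor bands onto one virtual band. Coefficients may be negative (the
#' camera correction matrices attenuate redundant bands and second-order
#' harmonics with signed combinations).
#'
#' @param path Path to a whitespace- or comma-delimited text file.
#' @return A list with `M` (`K x B` matrix) and `out_band_centers`
#'   (length-`K`), of class `correction_matrix`.
#' @export
load_correction_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("correction matrix file needs >= 2 rows")
  parse_row <- function(x) as.numeric(strsplit(trimws(x), "[,;[:space:]]+")[[1]])
  centers <- parse_row(lines[1])
  rows <- lapply(lines[-1], parse_row)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L)
    stop("ragged coefficient rows in correction matrix file")
  K <- length(rows); B <- widths[1]
  if (length(centers) != K)
    stop("first row must hold K output band centers (got ", length(centers),
         ", expected ", K, ")")
  if (K > 1L && any(diff(centers) <= 0))
    stop("output band centers must be strictly increasing")
  if (K > B) stop("correction matrix must satisfy K <= B")
  M <- do.call(rbind, rows)
  if (any(!is.finite(M))) stop("non-numeric entry in correction matrix file")
  correction_matrix(M, centers)
}

#' Construct a spectral-correction matrix object
#' @param M `K x B` numeric matrix.
#' @param out_band_centers Length-`K` strictly increasing wavelengths (nm).
#' @return Object of class `correction_matrix`.
#' @export
correction_matrix <- function(M, out_band_centers) {
  M <- as.matrix(M)
  if (nrow(M) != length(out_band_centers))
    stop("out_band_centers length must equal nrow(M)")
  if (nrow(M) > ncol(M)) stop("correction matrix must satisfy K <= B")
  if (nrow(M) > 1L && any(diff(out_band_centers) <= 0))
    stop("output band centers must be strictly increasing")
  structure(list(M = M, out_band_centers = as.numeric(out_band_centers)),
            class = "correction_matrix")
}

#' Write a correction matrix in the delimited-text exchange format
#' @param cm A `correction_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correction_matrix <- function(cm, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(sprintf("%.17g", cm$out_band_centers), collapse = " "), con)
  for (i in seq_len(nrow(cm$M)))
    writeLines(paste(sprintf("%.17g", cm$M[i, ]), collapse = " "), con)
  invisible(path)
}
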