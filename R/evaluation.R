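# Reflectance-quality evaluation: per-patch mean spectra, the MAE and
# spectral-angle metrics, the exhaustive learning/test patch-split search,
# and aggregation into summary tables.

#' Mean spectrum of a labelled patch
#'
#' @param cube A [reflectance_cube()] (or [radiance_cube()]).
#' @param patches Integer `H x W` label map (0 = none).
#' @param patch_id Patch label to average.
#' @return A list (`patch_id`, `spectrum`, `n_pixels`) of class
#'   `patch_spectrum`.
#' @export
patch_mean_spectrum <- function(cube, patches, patch_id) {
  sel <- patches == patch_id
  if (!any(sel)) stop("patch ", patch_id, " is empty")
  d <- dim(cube$values)
  spec <- vapply(seq_len(d[3]), function(b) mean(cube$values[, , b][sel]),
                 numeric(1))
  structure(list(patch_id = patch_id, spectrum = spec, n_pixels = sum(sel)),
            class = "patch_spectrum")
}

#' Mean absolute error between two spectra, in percent
#'
#' `MAE = 100/K * sum_k |ref_k - est_k|`; sensitive to the scale of the
#' estimate, complementary to the scale-free spectral angle.
#'
#' @param ref,est Numeric spectra of equal length.
#' @return MAE as a percentage.
#' @export
mae <- function(ref, est) {
  if (length(ref) != length(est)) stop("spectra lengths differ")
  100 * mean(abs(ref - est))
}

#' Spectral angle between two spectra, in radians
#'
#' `arccos(<ref, est> / (||ref|| ||est||))`, the cosine clamped to
#' `[-1, 1]` before `acos`; zero iff the spectra are collinear, hence a
#' scale-insensitive shape error.
#'
#' @param ref,est Numeric spectra of equal length, both nonzero.
#' @return Angle in radians.
#' @export
angular_error <- function(ref, est) {
  if (length(ref) != length(est)) stop("spectra lengths differ")
  nr <- sqrt(sum(ref^2)); ne <- sqrt(sum(est^2))
  if (nr == 0 || ne == 0) stop("angular error undefined for a zero vector")
  acos(.clamp(sum(ref * est) / (nr * ne), -1, 1))
}

#' Number of learning/test combinations of an exhaustive split
#' @param n Total patch count.
#' @param k Learning-subset size.
#' @return `choose(n, k)` as a double.
#' @export
n_split_combinations <- function(n, k) choose(n, k)

#' Exhaustive learning/test patch-split search
#'
#' Enumerates every size-`n_choose` learning subset of the reference
#' patches; for each, `est_provider(learning_ids)` must return the
#' estimated spectra of the complementary test patches (a `K x n_test`
#' matrix, columns ordered by ascending test id), and the criterion is the
#' mean MAE over those test patches. The subset minimising the criterion is
#' returned; ties resolve to the lexicographically smallest id set (the
#' enumeration order).
#'
#' @param ref_spectra `K x P` matrix of reference patch spectra, columns
#'   named or indexed by patch id `1..P`.
#' @param est_provider `function(learning_ids) -> K x (P - n_choose)` matrix.
#' @param n_choose Learning-subset size (default `P/2`).
#' @return A list (`learning_ids`, `test_ids`, `criterion_value`,
#'   `n_combinations_examined`) of class `split_result`.
#' @export
exhaustive_split <- function(ref_spectra, est_provider,
                             n_choose = ncol(ref_spectra) %/% 2) {
  P <- ncol(ref_spectra)
  if (n_choose < 1 || n_choose >= P) stop("n_choose must be in [1, P-1]")
  ids <- seq_len(P)
  combos <- utils::combn(ids, n_choose)
  best <- NULL; best_val <- Inf
  for (i in seq_len(ncol(combos))) {
    learn <- combos[, i]
    test <- setdiff(ids, learn)
    est <- tryCatch(est_provider(learn), error = function(e)
      stop("estimate provider failed on subset {",
           paste(learn, collapse = ","), "}: ", conditionMessage(e)))
    crit <- mean(vapply(seq_along(test), function(j)
      mae(ref_spectra[, test[j]], est[, j]), numeric(1)))
    if (crit < best_val) { best_val <- crit; best <- learn }
  }
  n_exam <- ncol(combos)
  stopifnot(n_exam == n_split_combinations(P, n_choose))
  structure(list(learning_ids = best,
                 test_ids = setdiff(ids, best),
                 criterion_value = best_val,
                 n_combinations_examined = n_exam),
            class = "split_result")
}

#' Aggregate per-patch errors into a per-method summary table
#'
#' @param per_patch Data frame with a `method` column and numeric error
#'   columns (e.g. `mae`, `dtheta`), one row per (patch, method).
#' @return Data frame of unweighted per-method means.
#' @export
aggregate_errors <- function(per_patch) {
  if (nrow(per_patch) == 0) stop("empty error table")
  num_cols <- names(per_patch)[vapply(per_patch, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "method")
  methods <- unique(per_patch$method)
  rows <- lapply(methods, function(m) {
    sub <- per_patch[per_patch$method == m, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("dropping empty method group: ", m)
      return(NULL)
    }
    cbind(data.frame(method = m),
          as.data.frame(as.list(colMeans(sub[num_cols]))))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
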