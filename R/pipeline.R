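# End-to-end conveniences tying the modules together.

#' Simulate a complete linescan acquisition of a scene
#'
#' Chooses the exposure with [auto_exposure()] when `tau` is `NULL`, then
#' runs the direct formation model.
#'
#' @inheritParams acquire_frames
#' @param tau Integration time; `NULL` for automatic exposure.
#' @return The assembled quantized [radiance_cube()].
#' @export
simulate_acquisition <- function(scene, illum, atten, config,
                                 dark = dark_model(), tau = NULL) {
  if (is.null(tau)) tau <- auto_exposure(scene, illum, atten, config, dark)
  simulate_direct(scene, illum, atten, config, tau, dark)
}

#' Dispatch a reflectance estimator by name
#'
#' @param cube Scene [radiance_cube()]; already vignetting-corrected for
#'   the single-reference methods (`wa`, `ms`, `rw`, `dwd`, `wn`).
#' @param masks A [mask_set()].
#' @param method One of `"ref"`, `"wa"`, `"ms"`, `"rw"`, `"dwd"`, `"wn"`.
#' @param rho_wd White-diffuser reflection factor.
#' @param m Top-value count for row medians.
#' @param white_cube Full-field white cube (required by `"ref"`).
#' @param wiener A fitted `wiener_model` (required by `"wn"`).
#' @return A [reflectance_cube()].
#' @export
estimate_reflectance <- function(cube, masks,
                                 method = c("rw", "wa", "ms", "ref",
                                            "dwd", "wn"),
                                 rho_wd = 0.95, m = 11L,
                                 white_cube = NULL, wiener = NULL) {
  method <- match.arg(method)
  switch(method,
    ref = {
      if (is.null(white_cube)) stop("method 'ref' needs a white cube")
      estimate_ref(cube, white_cube, rho_wd)
    },
    wa = estimate_wa(cube, masks$ws, rho_wd),
    ms = estimate_ms(cube, masks$wd | masks$patches > 0),
    rw = estimate_rw(cube, masks$wd, rho_wd, m),
    dwd = estimate_dwd(cube, masks$wd, masks$wp, rho_wd, m),
    wn = {
      if (is.null(wiener)) stop("method 'wn' needs a fitted wiener model")
      wiener_apply(wiener, cube)
    })
}
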