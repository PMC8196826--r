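test_that("full-field white-reference estimation recovers reflectance", {
  cfg <- t_cfg()
  s <- sim_setup(cfg)
  # cube == white cube at equal tau -> rho_wd everywhere
  same <- estimate_ref(s$white_cube, s$white_cube, cfg$rho_wd)
  expect_true(all(same$values == cfg$rho_wd))
  # tau_wd = 2 tau halves the radiance needed for equal estimates
  r1 <- estimate_ref(s$cube, s$white_cube, cfg$rho_wd, tau = 1, tau_wd = 1)
  r2 <- estimate_ref(s$cube, s$white_cube, cfg$rho_wd, tau = 1, tau_wd = 2)
  expect_equal(r2$values, 2 * r1$values)
  # noise-free constant-illumination recovery within 1 LSB / signal
  est <- estimate_ref(s$cube, s$white_cube, cfg$rho_wd)
  expect_lt(max(abs(est$values - s$scene$reflectance)),
            1 / min(s$white_cube$values))
  expect_warning(
    estimate_ref(s$cube,
                 radiance_cube(s$white_cube$values * 0,
                               s$white_cube$band_centers), cfg$rho_wd),
    "zero")
})

test_that("white-average estimation is exact under constant illumination only", {
  cfg <- t_cfg()
  s <- sim_setup(cfg)
  est <- estimate_wa(s$cube, s$scene$masks$ws, cfg$rho_wd)
  expect_lt(max(abs(est$values - s$scene$reflectance)),
            1 / min(s$cube$values[rep(s$scene$masks$wd, cfg$B)]))
  # WD pixels map close to rho_wd (self-consistency)
  expect_equal(mean(est$values[rep(s$scene$masks$wd, cfg$B)]), cfg$rho_wd,
               tolerance = 1e-3)
  expect_error(estimate_wa(s$cube, s$scene$masks$ws & FALSE), "empty")
  # under drift, wa degrades while rw does not
  sd20 <- sim_setup(cfg, illum_model = "linear_drift", amplitude = 0.2,
                    scene = s$scene)
  wa20 <- estimate_wa(sd20$cube, s$scene$masks$ws, cfg$rho_wd)
  rw20 <- estimate_rw(sd20$cube, s$scene$masks$wd, cfg$rho_wd, m = 3)
  expect_gt(scene_mae(wa20, s$scene), scene_mae(rw20, s$scene))
})

test_that("max-spectral estimation needs a white object to be unbiased", {
  cfg <- t_cfg()
  s <- sim_setup(cfg)   # patch scene: the white patch (0.92) sits in X
  excl <- s$scene$masks$wd
  est <- estimate_ms(s$cube, excl)
  # recovery up to the white object's reflectance as scale factor
  scale <- max(s$scene$reflectance[!excl])
  px <- !excl
  expect_equal(est$values[rep(px, cfg$B)] * scale,
               s$scene$reflectance[rep(px, cfg$B)], tolerance = 5e-3)
  # all-equal channel -> unity
  flat <- radiance_cube(array(7, dim = c(4, 4, 2)), c(500, 600))
  estf <- estimate_ms(flat, matrix(FALSE, 4, 4))
  expect_true(all(estf$values == 1))
  # vegetation-only scene: visible-band estimates biased high
  veg <- make_vegetation_scene(40, 64, cfg, classes = 2, seed = 8)
  sv <- sim_setup(cfg, scene = veg)
  estv <- estimate_ms(sv$cube, veg$masks$wd)
  vis_band <- 2  # well below the red edge
  veg_px <- veg$masks$classes > 0
  bias <- mean(estv$values[, , vis_band][veg_px] -
               veg$reflectance[, , vis_band][veg_px])
  expect_gt(bias, 0)
  expect_error(estimate_ms(flat, matrix(TRUE, 4, 4)), "empty")
})

test_that("row-wise estimation recovers reflectance under arbitrary illumination", {
  cfg <- t_cfg()
  base <- make_patch_scene(40, 64, cfg, n_patches = 6, seed = 3)
  for (model in c("linear_drift", "sinusoid", "step")) {
    s <- sim_setup(cfg, illum_model = model, amplitude = 0.25, scene = base)
    est <- estimate_rw(s$cube, base$masks$wd, cfg$rho_wd, m = 3)
    bound <- 1 / min(s$cube$values[rep(base$masks$wd, cfg$B)])
    expect_lt(max(abs(est$values - base$reflectance)), bound)
    # WD pixels map to ~rho_wd in every row
    wd_err <- abs(est$values[rep(base$masks$wd, cfg$B)] - cfg$rho_wd)
    expect_lt(max(wd_err), bound)
  }
  # constant illumination: rw and wa agree up to their denominator statistics
  s0 <- sim_setup(cfg, scene = base)
  rw0 <- estimate_rw(s0$cube, base$masks$wd, cfg$rho_wd, m = 3)
  wa0 <- estimate_wa(s0$cube, base$masks$ws, cfg$rho_wd)
  expect_lt(max(abs(rw0$values - wa0$values)), 0.01)
  # row coverage and m contracts
  no_row <- base$masks$wd; no_row[3, ] <- FALSE
  expect_error(estimate_rw(s0$cube, no_row, cfg$rho_wd, m = 3), "every image row")
  expect_error(estimate_rw(s0$cube, base$masks$wd, cfg$rho_wd, m = 100),
               "exceeds")
})

test_that("double-reference estimation normalizes through the white patch", {
  cfg <- t_cfg()
  s <- sim_setup(cfg)
  rw <- estimate_rw(s$cube, s$scene$masks$wd, cfg$rho_wd, m = 3)
  dwd <- estimate_dwd(s$cube, s$scene$masks$wd, s$scene$masks$wp,
                      cfg$rho_wd, m = 3)
  expect_true(all(dwd$values <= 1))
  # WP pixels map to ~1 after normalization
  expect_equal(mean(dwd$values[rep(s$scene$masks$wp, cfg$B)]), 1,
               tolerance = 1e-2)
  # constant illumination: dwd == rw up to a per-band normalization constant
  # (compare on unclipped pixels)
  for (b in seq_len(cfg$B)) {
    sel <- dwd$values[, , b] < 1 - 1e-9
    ratio <- dwd$values[, , b][sel] / rw$values[, , b][sel]
    expect_lt(diff(range(ratio)), 5e-3)
  }
  expect_error(estimate_dwd(s$cube, s$scene$masks$wd,
                            s$scene$masks$wp & FALSE, cfg$rho_wd, 3), "WP")
})

test_that("wiener transform solves the centered least-squares problem", {
  set.seed(4)
  K <- 3; n <- 12
  ref <- matrix(runif(K * n, 0.1, 0.9), K, n)
  # identity relation: G acts as identity on the span of centered columns
  fit <- wiener_fit(ref, ref)
  centered <- ref - rowMeans(ref)
  expect_equal(fit$G %*% centered, centered, tolerance = 1e-8)
  # diagonal camera model: G recovers D^{-1} exactly when spectra span R^K
  D <- diag(c(2, 0.5, 1.5))
  rad <- D %*% ref
  fit2 <- wiener_fit(ref, rad)
  expect_equal(fit2$G, solve(D), tolerance = 1e-8)
  # duplicate columns do not crash (pseudo-inverse path)
  dup <- ref[, c(1, 1, 2, 2, 3, 3)]
  expect_silent(wiener_fit(dup, dup))
  expect_error(wiener_fit(ref[, 1, drop = FALSE], rad[, 1, drop = FALSE]),
               "2 training")
})

test_that("wiener application reproduces training spectra and projects outside them", {
  set.seed(5)
  K <- 3; n <- 8
  ref <- matrix(runif(K * n, 0.1, 0.9), K, n)
  D <- diag(c(1.5, 0.8, 2))
  rad <- D %*% ref
  fit <- wiener_fit(ref, rad)
  # training patches laid out as a 2 x 4 image are reproduced exactly
  cube <- radiance_cube(array(t(rad), dim = c(2, 4, K)), c(500, 600, 700))
  est <- wiener_apply(fit, cube)
  expect_equal(array(t(ref), dim = c(2, 4, K)), est$values, tolerance = 1e-8)
  # constant cube at mean_rad -> mean_ref everywhere
  cm <- radiance_cube(array(rep(fit$mean_rad, each = 4), dim = c(2, 2, K)),
                      c(500, 600, 700))
  estm <- wiener_apply(fit, cm)
  for (k in seq_len(K))
    expect_equal(unique(as.vector(estm$values[, , k])), fit$mean_ref[k])
  # rank-deficient training (n < K after centering): outputs stay in the
  # span of the centered training reflectances
  ref2 <- matrix(runif(4 * 3, 0.1, 0.9), 4, 3)
  rad2 <- ref2 * 1.3
  fit2 <- wiener_fit(ref2, rad2)
  probe <- radiance_cube(array(runif(4), dim = c(1, 1, 4)), 1:4)
  out <- wiener_apply(fit2, probe)$values[1, 1, ] - fit2$mean_ref
  Tc <- ref2 - rowMeans(ref2)
  resid <- out - Tc %*% (MASS::ginv(Tc) %*% out)  # projector onto col(Tc)
  expect_lt(max(abs(resid)), 1e-8)
  expect_error(wiener_apply(fit, radiance_cube(array(1, c(2, 2, 4)), 1:4)),
               "channel")
})

test_that("spectral correction maps raw bands onto virtual bands", {
  cube <- radiance_cube(array(rep(c(1, 3, 5, 7), each = 4), dim = c(2, 2, 4)),
                        c(500, 600, 700, 800))
  idm <- correction_matrix(diag(4), c(500, 600, 700, 800))
  expect_equal(spectral_correct(cube, idm)$values, cube$values)
  pm <- correction_matrix(rbind(c(.5, .5, 0, 0), c(0, 0, .5, .5)),
                          c(550, 750))
  out <- spectral_correct(cube, pm)
  expect_equal(out$values[1, 1, ], c(2, 6))
  expect_equal(out$band_centers, c(550, 750))
  # negative coefficients can produce negative outputs
  nm <- correction_matrix(rbind(c(1, -1.5, 0, 0), c(0, 0, 1, 0)), c(550, 700))
  expect_lt(min(spectral_correct(cube, nm)$values), 0)
  # reflectance cubes keep their method tag and gain the corrected flag
  rc <- reflectance_cube(cube$values, cube$band_centers, method = "rw")
  rout <- spectral_correct(rc, pm)
  expect_identical(rout$method, "rw")
  expect_true(rout$spectrally_corrected)
  expect_error(spectral_correct(cube, correction_matrix(diag(3), 1:3)),
               "channels")
})

test_that("negative removal medians only negative pixels from the original image", {
  vals <- array(0.5, dim = c(5, 5, 1))
  rc <- reflectance_cube(vals, 500, method = "rw")
  expect_identical(remove_negatives(rc)$values, vals)  # identity when clean
  vals[3, 3, 1] <- -0.1
  rc <- reflectance_cube(vals, 500, method = "rw")
  out <- remove_negatives(rc)
  expect_equal(out$values[3, 3, 1], 0.5)               # median of neighbors
  expect_equal(out$values[-13], vals[-13])             # others untouched
  expect_true(out$negatives_removed)
  # a fully negative 3x3 block keeps (still negative) medians, with warning
  vals2 <- array(0.5, dim = c(7, 7, 1))
  vals2[3:5, 3:5, 1] <- -0.2
  rc2 <- reflectance_cube(vals2, 500, method = "wa")
  expect_warning(out2 <- remove_negatives(rc2), "remain")
  expect_lt(out2$values[4, 4, 1], 0)
  # idempotent on its own output apart from such blocks
  clean <- remove_negatives(rc)
  expect_identical(remove_negatives(clean)$values, clean$values)
})
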