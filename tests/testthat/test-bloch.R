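test_that("hard-pulse integrator matches closed forms and conserves norm", {
  n <- 500
  samp <- list(pos = matrix(0, 1, 3), b1 = matrix(1 + 0i, 1, 1), db0 = 0)
  # zero RF -> zero flip
  wf0 <- make_wf(matrix(0i, n, 1), matrix(0, n, 3), 2)
  expect_equal(bloch_simulate(wf0, NULL, 0, samp)$flip[1, 1], 0)
  # on-resonance 5 uT for 1 ms -> gamma * B1 * tau = 76.6 degrees
  wf <- make_wf(matrix(5 + 0i, n, 1), matrix(0, n, 3), 2)
  sim <- bloch_simulate(wf, NULL, 0, samp)
  expect_equal(sim$flip[1, 1], 76.64, tolerance = 1e-4)
  # rotations only: unit magnetization norm
  expect_equal(Mod(sim$mxy[1, 1])^2 + sim$mz[1, 1]^2, 1, tolerance = 1e-9)
})

test_that("integrator agrees with a matrix-exponential propagator", {
  set.seed(3)
  n <- 3; n_t <- 50
  b1 <- random_complex_matrix(n, 1, 3)
  rf <- 3 * random_complex_matrix(n_t, 1, 4)
  grad <- matrix(rnorm(n_t * 3, 0, 5), n_t, 3)
  pos <- matrix(rnorm(n * 3, 0, 50), n, 3)
  off <- rnorm(n, 0, 100)
  wf <- make_wf(rf, grad, 10)
  sim <- bloch_simulate(wf, NULL, 0, list(pos = pos, b1 = b1, db0 = off))
  gamma <- 2 * pi * 42.577e6; dt <- 10e-6
  for (v in 1:n) {
    M <- c(0, 0, 1)
    for (t in 1:n_t) {
      b <- b1[v, 1] * rf[t, 1] * 1e-6
      w <- c(gamma * Re(b), gamma * Im(b),
             2 * pi * off[v] + gamma * sum(grad[t, ] * 1e-3 * pos[v, ] * 1e-3))
      Omega <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0),
                      3, 3, byrow = TRUE)
      M <- as.vector(as.matrix(Matrix::expm(Omega * dt)) %*% M)
    }
    expect_equal(c(Re(sim$mxy[v, 1]), Im(sim$mxy[v, 1]), sim$mz[v, 1]), M,
                 tolerance = 1e-6)
  }
})

test_that("FWHM extraction recovers trapezoid geometry and flags edge cases", {
  # ideal 48 mm passband with 10% transitions: half-max mid-transition
  z <- seq(-60, 60, by = 0.5)
  prof <- pmin(1, pmax(0, (28.8 - abs(z)) / 4.8))
  fw <- profile_fwhm(z, prof)
  expect_equal(fw$fwhm, 52.8, tolerance = 1e-6)
  # scaling the profile leaves the FWHM unchanged
  fw2 <- profile_fwhm(z, 13 * prof)
  expect_equal(fw2$fwhm, fw$fwhm, tolerance = 1e-9)
  # a uniform nonzero profile has no half crossing
  expect_true(profile_fwhm(z, rep(2, length(z)))$undefined)
})

test_that("slab profile of the designed pulse is centered and slab-sized", {
  ev <- fix_metrics4d()  # forces the design fixture
  sim <- evaluate_design(fix_design4d()$wf, fix_cal(), fix_regions())$result
  pr <- slab_profile(sim)
  expect_false(pr$undefined)
  # effective thickness within 25% of the 52.8 mm prescription at the
  # coarse 8 mm evaluation grid
  expect_lt(abs(pr$fwhm - 52.8), 0.25 * 52.8)
  # profile peaks inside the slab
  expect_lt(abs(pr$position[which.max(pr$flip)]), 24)
})

test_that("spectral response sweep has the prescribed sampling", {
  ph <- phantom_calibration(grid_geometry(c(20, 20, 20), 10), 170, 1)
  rg <- define_regions(ph, 0, 48)
  des <- design_spsp4d(ph, rg, limits = fix_limits(), iw_inplane = 20,
                       sb_inplane = 40, sb_throughplane = 30,
                       max_iter = 150)
  rsp <- spsp_response(des$wf, ph)
  # -1300..300 in steps of 100 -> 17 native offsets
  expect_length(rsp$freqs_native, 17)
  expect_equal(ncol(rsp$response), 161)
  # interpolation reproduces native samples exactly
  i100 <- match(rsp$freqs_native, rsp$freqs)
  expect_equal(rsp$response[, i100], rsp$intensity_native, tolerance = 1e-12)
  # in-slab stopband response is far below the water passband response
  in_z <- abs(rsp$z_mm) <= 24
  pass <- mean(rsp$response[in_z, rsp$freqs == 0])
  stopb <- mean(rsp$response[in_z, rsp$freqs %in% rg$fat_freqs])
  expect_lt(stopb, pass / 3)
  expect_error(spsp_response(des$wf, ph, interp_step = 200), "interp_step")
})

test_that("gradient-delay scan is anchored at zero delay and hits fat first", {
  ds <- delay_scan(fix_design4d()$wf, fix_cal(), fix_regions(),
                   delays_us = c(-5, 0, 5), eval_res = 16)
  # delta = 0 equals the undelayed metrics computed on the same raster
  wf1 <- ptxspsp:::upsample_waveform(fix_design4d()$wf, 20L)
  rg <- fix_regions()
  s_iw <- downsample_region(fix_cal(), rg$mask_inslab_water, 16, 16)
  s_ow <- downsample_region(fix_cal(), rg$mask_outslab_water, 16, 16)
  f_iw <- bloch_simulate(wf1, fix_cal(), 0, s_iw)$flip
  f_ow <- bloch_simulate(wf1, fix_cal(), 0, s_ow)$flip
  ref <- sqrt(mean(c((f_iw - ernst_angle())^2, f_ow^2)))
  expect_equal(ds$rmse_water[ds$delay_us == 0], ref, tolerance = 1e-12)
  # fat suppression degrades with delay, and faster than water excitation
  r0 <- ds[ds$delay_us == 0, ]
  for (d in c(-5, 5)) {
    rd <- ds[ds$delay_us == d, ]
    expect_gt(rd$rmse_fat, r0$rmse_fat)
    expect_gt(rd$rmse_fat / r0$rmse_fat, rd$rmse_water / r0$rmse_water)
  }
  # default grid covers -5..5 in steps of 1 -> 11 delays
  expect_length(formals(delay_scan)$delays_us |> eval(), 11)
})
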