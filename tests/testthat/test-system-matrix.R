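test_that("STA matrix reproduces the hard-pulse closed form", {
  # constant 5 uT for 1 ms on resonance: flip = gamma * B1 * tau = 76.6 deg
  n <- 500
  wf <- make_wf(matrix(5 + 0i, n, 1), matrix(0, n, 3), raster_us = 2)
  samp <- list(pos = matrix(0, 1, 3), b1 = matrix(1 + 0i, 1, 1), db0 = 0)
  A <- sta_matrix(samp, 0, wf)
  flip <- Mod(A %*% rep(5 + 0i, n))
  expect_equal(as.vector(flip), 2 * pi * 42.577e6 * 5e-6 * 1e-3 * 180 / pi,
               tolerance = 1e-9)
  expect_equal(as.vector(flip), 76.64, tolerance = 1e-4)
  # linearity in the RF vector
  x1 <- complex(real = rnorm(n), imaginary = rnorm(n))
  x2 <- complex(real = rnorm(n), imaginary = rnorm(n))
  expect_equal(A %*% (x1 + x2), A %*% x1 + A %*% x2, tolerance = 1e-12)
  # zero RF -> zero response
  expect_true(all(Mod(A %*% rep(0i, n)) == 0))
  expect_error(sta_matrix(samp, numeric(0), wf), "empty frequency")
})

test_that("design matrices have the prescribed dimensions and row layout", {
  # 8 channels x 1500 RF samples -> 12000 columns
  sg <- bipolar_slab_gradient()
  lim <- hardware_limits(raster_us = 2)
  wf <- assemble_waveforms(sg, NULL, NULL, lim)
  samp <- list(pos = matrix(rnorm(9), 3, 3),
               b1 = matrix(complex(real = rnorm(24), imaginary = rnorm(24)),
                           3, 8),
               db0 = rnorm(3))
  A <- sta_matrix(samp, 0, wf)
  expect_equal(ncol(A), 12000)
  expect_equal(nrow(A), 3)

  # fat rows: n_samples x 5 frequencies, frequency-major ordering
  A5 <- sta_matrix(samp, c(-1200, -1100, -1000, -900, -800), wf)
  expect_equal(nrow(A5), 15)
  meta <- attr(A5, "meta")
  expect_equal(meta$freq[1:3], rep(-1200, 3))
  expect_equal(unique(meta$freq), c(-1200, -1100, -1000, -900, -800))
})

test_that("the four-region problem excludes don't-care voxels", {
  cal <- fix_cal()
  rg <- fix_regions()
  prob <- fix_design4d()$problem
  # no design row lies in the transition band along the slab axis
  for (m in list(attr(prob$A_iw, "meta"), attr(prob$A_ow, "meta"))) {
    z <- m[, c("x", "y", "z")][[cal$grid$slab_axis]]
    expect_true(all(abs(z) <= 24 | abs(z) > 24 + 4.8))
  }
  # fat block covers all five stopband frequencies
  expect_equal(unique(attr(prob$A_f, "meta")$freq), rg$fat_freqs)
  # all three matrices share the unknown dimension
  expect_equal(ncol(prob$A_iw), ncol(prob$A_ow))
  expect_equal(ncol(prob$A_iw), ncol(prob$A_f))
})

test_that("halving stopband down-sampling quadruples the row count", {
  # on a mask filling whole cells, 18 -> 9 mm in-plane gives 4x the samples
  g <- grid_geometry(c(24, 24, 8), 3)
  cal <- generate_calibration(2, g, seed = 1)
  cal$mask_brain[] <- TRUE
  s18 <- downsample_region(cal, cal$mask_brain, 18, 12)
  s9 <- downsample_region(cal, cal$mask_brain, 9, 12)
  expect_equal(nrow(s9$pos), 4 * nrow(s18$pos))
})

test_that("translating samples leaves the response magnitude invariant", {
  # |A x| depends on position only through phases; a common translation
  # multiplies each row by a unit phase and leaves magnitudes unchanged
  set.seed(11)
  n <- 200
  grad <- matrix(rnorm(3 * n, 0, 3), n, 3)
  wf <- make_wf(matrix(0i, n, 2), grad, raster_us = 10)
  samp <- list(pos = matrix(rnorm(15, 0, 20), 5, 3),
               b1 = random_complex_matrix(5, 2, 3), db0 = rep(0, 5))
  d <- c(7, -4, 11)
  samp_shift <- samp
  samp_shift$pos <- sweep(samp$pos, 2, d, "+")
  A1 <- sta_matrix(samp, 0, wf)
  A2 <- sta_matrix(samp_shift, 0, wf)
  x <- complex(real = rnorm(ncol(A1)), imaginary = rnorm(ncol(A1)))
  # columns of the shifted matrix pick up exp(i k_j . d); compensating the
  # RF vector with the conjugate phases restores the response magnitude
  kb <- gradient_to_k(grad, 10)
  k_mid <- (kb[1:n, ] + kb[2:(n + 1), ]) / 2
  col_phase <- rep(exp(-1i * as.vector(k_mid %*% (d * 1e-3))), 2)
  expect_equal(Mod(A2 %*% (x * col_phase)), Mod(A1 %*% x),
               tolerance = 1e-9)
})

test_that("STA prediction matches Bloch simulation in the small-tip regime", {
  cal <- generate_calibration(8, grid_geometry(c(16, 16, 16), 12), seed = 4)
  rg <- define_regions(cal, 0, 48)
  lim <- hardware_limits(raster_us = 2)
  sg <- bipolar_slab_gradient(limits = lim)
  k2 <- spins_inplane_trajectory(spins_params(t_p = sg$t_osc_ms), 2)
  ip <- k_to_gradient(k2, 2, lim)
  wf0 <- assemble_waveforms(sg, ip$grad, NULL, lim,
                            slab_axis = cal$grid$slab_axis)
  n_t <- length(wf0$rf_support)
  tt <- seq_len(n_t) / n_t
  # smooth arbitrary multi-channel RF, scaled to <= 5 degree flips
  x <- unlist(lapply(1:8, function(c)
    complex(real = sin(2 * pi * tt * c / 2), imaginary = cos(6 * pi * tt)) *
      exp(2i * pi * c / 8)))
  samp <- downsample_region(cal, rg$mask_inslab_water, 24, 24)
  A <- sta_matrix(samp, 0, wf0)
  x <- x * (4.5 / max(Mod(A %*% x)))
  sta <- as.vector(Mod(A %*% x))
  bloch <- bloch_simulate(set_rf(wf0, x, 8), cal, 0,
                          positions = samp)$flip[, 1]
  expect_lt(max(abs(bloch - sta) / sta), 0.05)
})
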