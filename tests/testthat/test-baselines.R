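test_that("spoke slab gradient amplitude follows the bandwidth relation", {
  # TBWP 6 over 0.3 ms -> 20 kHz; over 48 mm -> G = BW/(gamma_bar * dz)
  sp <- fix_spokes()
  expect_equal(sp$g_slab, 20000 / (42.577e6 * 0.048) * 1e3,
               tolerance = 1e-9)
  expect_equal(sp$g_slab, 9.79, tolerance = 1e-3)
  # six spokes: five on a circle, one at the k-space origin
  expect_equal(nrow(sp$kxy), 6)
  expect_equal(unname(sp$kxy[6, ]), c(0, 0))
  r <- sqrt(rowSums(sp$kxy[1:5, ]^2))
  expect_equal(r, rep(2 * pi / 0.24, 5), tolerance = 1e-9)
  # total duration matches the 4D design within the rewinder tolerance
  expect_lt(abs(sp$wf$t_total_ms - 3.2), 0.32)
})

test_that("in-plane excitation k reaches each spoke location at its center", {
  sp <- fix_spokes()
  wf <- sp$wf
  k <- waveform_k(wf)
  centers <- round((seq_len(6) - 0.5) * 0.5e3 / wf$raster_us) + 1L
  for (s in 1:6) {
    expect_equal(unname(k[centers[s], 1:2]), unname(sp$kxy[s, ]),
                 tolerance = 0.05)
  }
})

test_that("bipolar spokes leave out-of-slab fat excitation the 4D design removes", {
  m4 <- fix_metrics4d()
  msp <- fix_metrics_spokes()
  # spokes are blind to fat: substantially worse brain-wide fat RMSE
  # than the comprehensive design on the same calibration
  expect_gt(msp$rmse_fat, 1.5 * m4$rmse_fat)
  # while their water-only design keeps in-slab water reasonable
  expect_lt(msp$rmse_water_in, 2 * ernst_angle())
})

test_that("optimal TBWP: fly-back lobes cost about 70% at matched timing", {
  bi <- optimal_tbwp("bipolar", 0.5, 48)
  mo <- optimal_tbwp("monopolar", 0.5, 48)
  # monopolar strictly loses RF time to the fly-back
  expect_lt(mo$tbwp, bi$tbwp)
  red <- 100 * (1 - mo$tbwp / bi$tbwp)
  expect_lt(abs(red - 70), 10)
  # bipolar closed form: G* = tau * slew / 4, T_rf = tau / 2
  expect_equal(bi$g_mT, 25, tolerance = 1e-3)
  expect_equal(bi$tbwp, 42.577e6 * 25e-3 * 0.048 * 0.25e-3,
               tolerance = 1e-3)
})

test_that("optimal TBWP is monotone in inter-pulse time and amplitude limit", {
  taus <- c(0.4, 0.5, 0.6, 0.8)
  for (pol in c("bipolar", "monopolar")) {
    v <- vapply(taus, function(tt) optimal_tbwp(pol, tt, 48)$tbwp,
                numeric(1))
    expect_true(all(diff(v) > 0))
  }
  gmaxes <- c(20, 40, 70)
  v2 <- vapply(gmaxes, function(g)
    optimal_tbwp("monopolar", 0.5, 48,
                 hardware_limits(g_max = g))$tbwp, numeric(1))
  expect_true(all(diff(v2) >= 0))
  # infinite slew: the reduction collapses to the RF-time ratio set by
  # the fly-back area alone (fly-back at g_max)
  lim_inf <- hardware_limits(slew_max = 1e9)
  bi <- optimal_tbwp("bipolar", 0.5, 48, lim_inf)
  mo <- optimal_tbwp("monopolar", 0.5, 48, lim_inf)
  expect_equal(mo$tbwp / bi$tbwp, 0.5, tolerance = 0.01)
})

test_that("binomial composite hits the target on water and nulls fat", {
  # 1-5-10-10-5-1 with pi inter-pulse fat phase: alternating sum is zero
  co <- c(1, 5, 10, 10, 5, 1)
  expect_equal(sum(co * (-1)^(seq_along(co) - 1)), 0)

  grid <- grid_geometry(c(3, 3, 81), c(40, 40, 2))
  cal <- phantom_calibration(grid, 1e6, 1)
  wb <- design_binomial(polarity = "bipolar")
  expect_equal(attr(wb, "inter_pulse_ms"), 0.5)  # 1/(2*1000 Hz)
  sim <- bloch_simulate(wb, cal, 0)
  i0 <- which.min(rowSums(sim$pos^2))
  # on-resonance net flip at slab center equals the Ernst target
  expect_equal(sim$flip[i0, 1], ernst_angle(), tolerance = 0.02)
  # fat at -1000 Hz accrues pi between sub-pulses: near-complete null
  simf <- bloch_simulate(wb, cal, -1000)
  expect_lt(simf$flip[i0, 1], 0.1)
})

test_that("monopolar binomial trades slab sharpness for fat-phase consistency", {
  grid <- grid_geometry(c(3, 3, 81), c(40, 40, 2))
  cal <- phantom_calibration(grid, 1e6, 1)
  wb <- design_binomial(polarity = "bipolar")
  wm <- design_binomial(polarity = "monopolar")
  prof_b <- slab_profile(bloch_simulate(wb, cal, 0))
  prof_m <- slab_profile(bloch_simulate(wm, cal, 0))
  # both select roughly the nominal 48 mm slab
  expect_lt(abs(prof_b$fwhm - 48) / 48, 0.10)
  expect_lt(abs(prof_m$fwhm - 48) / 48, 0.15)
  # transition sharpness: width between 90% and 10% of the plateau level
  edge_width <- function(pr) {
    lvl <- pr$level
    z <- seq(min(pr$position), max(pr$position), length.out = 2000)
    v <- approx(pr$position, pr$flip, xout = z)$y
    right <- z > 0
    z90 <- z[right][which(v[right] < 0.9 * lvl)[1]]
    z10 <- z[right][which(v[right] < 0.1 * lvl)[1]]
    z10 - z90
  }
  # lower monopolar TBWP -> visibly wider transition band
  expect_gt(edge_width(prof_m), 1.5 * edge_width(prof_b))
})
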