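test_that("bipolar slab gradient has the prescribed timing and areas", {
  sg <- bipolar_slab_gradient(3, 1, 25, hardware_limits())
  # ramp at max slew: 25 mT/m / 200 T/m/s = 0.125 ms
  expect_equal(sg$ramp_ms, 0.125)
  # per-lobe area: plateau x (half period - ramp)
  expect_equal(sg$lobe_area, 25e-3 * 0.375e-3)
  expect_equal(sg$t_osc_ms, 3)
  # total duration ~3.2 ms (minimum-time rewinder), within 10%
  expect_lt(abs(sg$t_total_ms - 3.2), 0.32)

  # numerical integration of the emitted samples reproduces the lobe area
  gz <- sample_gradient(sg$breaks_s, sg$vals, 2)
  dt <- 2e-6
  first_lobe <- sum(gz[1:250]) * dt * 1e-3          # T*s/m
  expect_equal(first_lobe, sg$lobe_area, tolerance = 1e-4)

  expect_error(bipolar_slab_gradient(3, 1, 80), "g_max")
  expect_error(bipolar_slab_gradient(3, 0.4, 60), "ramps do not fit")
})

test_that("slab-axis excitation k is refocused at every lobe center", {
  sg <- bipolar_slab_gradient()
  lim <- hardware_limits()
  wf <- assemble_waveforms(sg, NULL, NULL, lim)
  kz <- waveform_k(wf)[, 3]
  # k(T) = 0 under the excitation convention
  expect_equal(kz[length(kz)], 0)
  # the half-area rewinder nulls kz at each sub-pulse (lobe) center
  centers <- round(sg$lobe_centers_ms * 1e3 / lim$raster_us) + 1L
  expect_lt(max(abs(kz[centers])) / max(abs(kz)), 1e-3)
  # excursion is symmetric about zero
  expect_equal(max(kz), -min(kz), tolerance = 0.01)
})

test_that("SPINS formula evaluates to its printed constants", {
  p <- spins_params()
  expect_equal(p$k_max, 20)
  # logistic midpoint: r at t = beta_s * t_p is k_max / 2
  expect_equal(spins_radius(0.5 * p$t_p, spins_params(t_p = 3)), 10)
  # r(0) = 20 / (1 + exp(-5))
  expect_equal(spins_radius(0, spins_params(t_p = 3)), 20 / (1 + exp(-5)),
               tolerance = 1e-12)
  # theta(0.5 ms) = 8 pi * 0.5 = 4 pi -> transverse k vanishes there
  k <- spins_inplane_trajectory(spins_params(t_p = 3), 2)
  t_ms <- attr(k, "times_ms")
  i <- which(t_ms == 0.5)
  expect_equal(unname(k[i, ]), c(0, 0), tolerance = 1e-9)
  # radius bounded by k_max
  expect_true(all(sqrt(rowSums(k^2)) <= 20 + 1e-9))
})

test_that("k-space to gradient conversion round-trips exactly", {
  lim <- hardware_limits()
  k <- spins_inplane_trajectory(spins_params(t_p = 3), 2)
  g <- k_to_gradient(k, 2, lim)
  k_rec <- gradient_to_k(g$grad, 2)
  # achieved trajectory equals the prescription shifted to end at zero
  k_shift <- sweep(k, 2, k[nrow(k), ], "-")
  expect_lt(max(abs(k_rec[seq_len(nrow(k)), ] - k_shift)), 1e-6)
  # gradient stays within limits without dilation
  expect_equal(g$dilation, 1L)

  # constant k over an interval -> zero gradient there
  k2 <- cbind(c(rep(5, 50), seq(5, 0, length.out = 51)), numeric(101))
  g2 <- k_to_gradient(k2, 10, lim)
  expect_true(all(g2$grad[1:49, 1] == 0))
  # k ending at zero -> no rewinder appended
  expect_equal(nrow(g2$grad), 100)
})

test_that("round trip holds on random smooth trajectories ending at zero", {
  lim <- hardware_limits()
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    t <- seq(0, 1, length.out = n + 1)
    k <- cbind(10 * sin(2 * pi * t * sample(1:3, 1)) * (1 - t),
               8 * sin(2 * pi * t * sample(2:4, 1)) * (1 - t))
    g <- k_to_gradient(k, 10, lim)
    k_rec <- gradient_to_k(g$grad, 10)
    expect_lt(max(abs(k_rec[seq_len(nrow(k)), ] - k)), 1e-9)
  }
})

test_that("waveform assembly validates sizes and hardware limits", {
  sg <- bipolar_slab_gradient()
  lim <- hardware_limits()
  k <- spins_inplane_trajectory(spins_params(t_p = 3), 2)
  ip <- k_to_gradient(k, 2, lim)
  # 3 pairs at 1 ms on a 2 us raster -> 1500-sample RF support
  wf <- assemble_waveforms(sg, ip$grad, NULL, lim)
  expect_length(wf$rf_support, 1500)
  # zero RF everywhere is a valid waveform set
  expect_s3_class(wf, "waveform_set")
  # per-axis amplitude and slew compliance of the emitted waveform
  expect_true(max(abs(wf$grad)) <= lim$g_max + 1e-9)
  expect_true(max(abs(apply(wf$grad, 2, diff))) / (2e-3) <= lim$slew_max + 1e-6)

  # injected over-limit amplitude is rejected
  bad <- wf
  bad$grad[100, 1] <- 71
  expect_error(validate_waveform(bad), "exceeds limit")
  # RF outside the support window is rejected
  bad2 <- wf
  bad2$rf[nrow(bad2$rf), 1] <- 1 + 0i
  expect_error(validate_waveform(bad2), "outside its support")
  # mismatched RF length is an assembly error
  expect_error(assemble_waveforms(sg, ip$grad, matrix(0i, 10, 2), lim),
               "assembly error")
})

test_that("designed waveforms from every module respect hardware limits", {
  for (wf in list(fix_design4d()$wf, fix_spokes()$wf,
                  design_binomial(polarity = "bipolar"),
                  design_binomial(polarity = "monopolar"))) {
    lim <- wf$limits
    expect_true(max(abs(wf$grad)) <= lim$g_max + 1e-6)
    dg <- abs(apply(wf$grad, 2, diff)) / (wf$raster_us * 1e-3)
    expect_true(max(dg) <= lim$slew_max + 1e-6)
  }
})

test_that("waveform export writes a readable table", {
  wf <- design_binomial(polarity = "bipolar")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_waveform(wf, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(wf$grad))
  expect_equal(tab$gz, wf$grad[, 3])
  expect_equal(tab$rf1_re, Re(wf$rf[, 1]))
  # full round trip through the text container
  wf2 <- read_waveform(f)
  expect_equal(wf2$grad, wf$grad, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(wf2$rf, wf$rf, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(wf2$raster_us, wf$raster_us)
  expect_equal(range(wf2$rf_support), range(wf$rf_support))
})
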