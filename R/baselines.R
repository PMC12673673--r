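#' Hann-windowed sinc sub-pulse envelope
#'
#' @param duration_ms sub-pulse duration, ms.
#' @param tbwp time-bandwidth product.
#' @param raster_us raster, microseconds.
#' @return real vector of unit-peak envelope samples at raster midpoints.
#' @export
sinc_subpulse <- function(duration_ms, tbwp, raster_us) {
  n <- max(1L, round(duration_ms * 1e3 / raster_us))
  t <- ((seq_len(n) - 0.5) / n - 0.5) * duration_ms * 1e-3   # s, centered
  bw <- tbwp / (duration_ms * 1e-3)                          # Hz
  env <- ifelse(t == 0, 1, sin(pi * bw * t) / (pi * bw * t))
  env * (0.5 + 0.5 * cos(2 * pi * t / (duration_ms * 1e-3)))
}

## minimal slab_gradient-like container from explicit breakpoints
make_slab_gradient <- function(breaks_s, vals, t_osc_ms, lobe_area,
                               lobe_centers_ms, limits) {
  structure(list(breaks_s = breaks_s, vals = vals,
                 t_osc_ms = t_osc_ms,
                 t_total_ms = max(breaks_s) * 1e3,
                 lobe_area = lobe_area, lobe_centers_ms = lobe_centers_ms,
                 limits = limits), class = "slab_gradient")
}

#' Traditional multi-spoke pTx spatial-spectral pulse design
#'
#' Designs the conventional comparison pulse: identical sinc sub-pulses
#' played on alternating-polarity (bipolar) slab-selective trapezoids at
#' several in-plane excitation k-space locations (spokes), with in-plane
#' gradient blips between spokes. Channel- and spoke-wise complex weights
#' are solved by regularized magnitude least squares on inside-slab water
#' samples only (a few calibration slices spanning the slab), which is
#' what leaves this design blind to out-of-slab fat behavior.
#'
#' @param cal a `calibration_set`.
#' @param regions a [define_regions()] result (supplies slab geometry).
#' @param n_spokes number of spokes; one is at the k-space origin, the
#'   rest on a circle of radius `2*pi/fox_mm`.
#' @param subpulse_ms sinc sub-pulse duration, ms (default 0.3).
#' @param tbwp sub-pulse time-bandwidth product (default 6).
#' @param fox_mm in-plane field of excitation setting the spoke radius.
#' @param period_ms slab-gradient oscillation period (one lobe per
#'   half-period; `n_spokes` lobes are used).
#' @param n_slices number of calibration slices spanning the slab used
#'   for the design (default 3).
#' @param inplane_res in-plane design down-sampling, mm.
#' @param alpha0 target in-slab flip, degrees.
#' @param beta_reg RF power regularization in the same units as the 4D
#'   design (applied to the physical RF waveform norm).
#' @param limits a [hardware_limits()].
#' @param tol,max_iter solver controls.
#' @return list with `wf` (designed `waveform_set`), `weights` (channel x
#'   spoke), `state` (the `solver_state`), `kxy` (spoke locations).
#' @export
design_spokes <- function(cal, regions, n_spokes = 6L, subpulse_ms = 0.3,
                          tbwp = 6, fox_mm = 240, period_ms = 1,
                          n_slices = 3L, inplane_res = 6,
                          alpha0 = ernst_angle(), beta_reg = 2000,
                          limits = hardware_limits(),
                          tol = 1e-6, max_iter = 200L) {
  if (n_spokes %% 2L != 0L)
    stop("spoke count must match the bipolar lobe count (even)")
  raster <- limits$raster_us
  dz_m <- regions$passband_width * 1e-3
  bw <- tbwp / (subpulse_ms * 1e-3)                    # Hz
  g_slab <- bw / (GAMMA_BAR * dz_m) * 1e3              # mT/m
  if (g_slab > limits$g_max) stop("slab gradient above amplitude limit")
  sg <- bipolar_slab_gradient(n_pairs = n_spokes %/% 2L,
                              period_ms = period_ms,
                              plateau = g_slab, limits = limits)
  half_ms <- period_ms / 2
  plateau_ms <- half_ms - 2 * sg$ramp_ms
  if (subpulse_ms > plateau_ms + 1e-9)
    stop("sub-pulse does not fit on the gradient plateau")

  ## spoke k-space locations: n-1 on a circle, last at the origin
  r_k <- 2 * pi / (fox_mm * 1e-3)                      # rad/m
  ang <- 2 * pi * (seq_len(n_spokes - 1L) - 1L) / (n_spokes - 1L)
  kxy <- rbind(cbind(r_k * cos(ang), r_k * sin(ang)), c(0, 0))

  ## blips between consecutive spokes, centered on the lobe boundaries
  n_total <- ceiling(sg$t_total_ms * 1e3 / raster)
  gxy <- matrix(0, n_total, 2)
  gap_ms <- 2 * sg$ramp_ms + (plateau_ms - subpulse_ms)
  for (s in seq_len(n_spokes - 1L)) {
    m_xy <- -(kxy[s, ] - kxy[s + 1L, ]) / GAMMA        # T*s/m per axis
    t_bound <- s * half_ms * 1e-3                      # s
    ## blips keep a 20% slew/amplitude margin so the exact-moment
    ## rescaling below cannot push them over the hardware limits
    blip_lim <- hardware_limits(0.8 * limits$g_max, 0.8 * limits$slew_max,
                                limits$raster_us)
    for (a in 1:2) {
      lb <- min_time_lobe(m_xy[a], blip_lim)
      if (lb$duration == 0) next
      if (lb$duration > gap_ms * 1e-3)
        stop("infeasible in-plane blip between spokes")
      br <- lb$breaks - lb$duration / 2 + t_bound
      i0 <- round(br[1] / (raster * 1e-6))
      nsamp <- ceiling(lb$duration / (raster * 1e-6) - 1e-9)
      blip <- sample_gradient(lb$breaks, lb$vals, raster, nsamp)
      # rescale so the discretized blip realizes the moment exactly
      blip <- blip * (m_xy[a] / (sum(blip) * 1e-3 * raster * 1e-6))
      gxy[i0 + seq_len(nsamp), a] <- gxy[i0 + seq_len(nsamp), a] + blip
    }
  }
  wf0 <- assemble_waveforms(sg, gxy, rf = NULL, limits = limits,
                            slab_axis = cal$grid$slab_axis)

  ## RF basis: unit sinc on each lobe plateau
  n_t <- length(wf0$rf_support)
  env <- sinc_subpulse(subpulse_ms, tbwp, raster)
  n_env <- length(env)
  basis <- matrix(0, n_t, n_spokes)
  for (s in seq_len(n_spokes)) {
    ctr <- (s - 0.5) * half_ms * 1e3 / raster          # samples
    i0 <- round(ctr - n_env / 2)
    basis[i0 + seq_len(n_env), s] <- env
  }

  ## in-slab design samples: n_slices slab-axis slices spanning the slab
  ax <- cal$grid$slab_axis
  zc <- grid_axis_coords(cal$grid, ax)
  in_z <- which(abs(zc - regions$slab_center) <= regions$passband_width / 2)
  pick <- in_z[unique(round(seq(1, length(in_z), length.out = n_slices)))]
  slice_mask <- array(FALSE, cal$grid$shape)
  idx <- which(regions$mask_inslab_water, arr.ind = TRUE)
  keep <- idx[, ax] %in% pick
  slice_mask[idx[keep, , drop = FALSE]] <- TRUE
  samp <- downsample_region(cal, slice_mask, inplane_res,
                            cal$grid$voxel_size[ax])
  if (nrow(samp$pos) == 0L) stop("empty in-slab design sample set")

  A_full <- sta_matrix(samp, regions$water_freqs, wf0)
  n_ch <- cal$n_channels
  B <- matrix(0, n_ch * n_t, n_ch * n_spokes)
  for (c in seq_len(n_ch))
    B[(c - 1L) * n_t + seq_len(n_t),
      (c - 1L) * n_spokes + seq_len(n_spokes)] <- basis
  A_spokes <- A_full %*% B
  ## power_scale maps ||weights||^2 to the integrated physical RF power
  prob <- structure(list(
    A_iw = A_spokes,
    A_ow = matrix(0i, 0, ncol(A_spokes)),
    A_f = matrix(0i, 0, ncol(A_spokes)),
    alpha0 = alpha0, lambda1 = 0, lambda2 = 0, beta_reg = beta_reg,
    power_scale = sum(env^2) * raster * 1e-6,
    n_channels = n_ch, n_t = n_spokes), class = "design_problem")
  st <- vem_solve(prob, init = "cp", tol = tol, max_iter = max_iter)
  w <- matrix(st$x, nrow = n_spokes, ncol = n_ch)    # spoke x channel
  rf <- basis %*% w                                  # n_t x n_ch, uT
  wf <- set_rf(wf0, as.vector(rf), n_ch)
  list(wf = wf, weights = t(w), state = st, kxy = kxy,
       g_slab = g_slab, basis = basis)
}

## per-amplitude TBWP of a binomial sub-pulse lobe; G in T/m
tbwp_lobe <- function(g, polarity, tau_s, dz_m, limits) {
  s <- limits$slew_max
  t_ramp <- g / s
  avail <- tau_s - 2 * t_ramp
  if (avail <= 0) return(list(tbwp = 0, t_rf = 0))
  if (polarity == "bipolar") {
    t_rf <- avail
  } else {
    gmax <- limits$g_max * 1e-3
    fb_time <- function(t_rf) {
      area <- g * (t_rf + t_ramp)
      peak <- sqrt(area * s)
      if (peak <= gmax) 2 * sqrt(area / s) else area / gmax + gmax / s
    }
    f <- function(t_rf) t_rf + fb_time(t_rf) - avail
    if (f(0) >= 0) return(list(tbwp = 0, t_rf = 0))
    t_rf <- uniroot(f, c(0, avail), tol = 1e-12)$root
  }
  list(tbwp = GAMMA_BAR * g * dz_m * t_rf, t_rf = t_rf)
}

#' Optimal (maximum feasible) sub-pulse time-bandwidth product
#'
#' For a binomial composite pulse with sub-pulses of fixed inter-pulse
#' spacing, finds the slab-selective gradient amplitude maximizing the
#' sub-pulse TBWP `= gamma_bar * G * dz * T_rf` subject to: RF only
#' during the plateau; maximum-slew ramps; for monopolar polarity a
#' minimum-time fly-back lobe of equal area must also fit within the
#' inter-pulse interval; amplitude and slew limits.
#'
#' @param polarity `"bipolar"` or `"monopolar"`.
#' @param inter_pulse_ms sub-pulse center spacing, ms.
#' @param slab_thickness_mm slab thickness, mm.
#' @param limits a [hardware_limits()].
#' @return list with `tbwp`, `g_mT` (optimal amplitude), `t_rf_ms`
#'   (plateau RF duration), `polarity`.
#' @examples
#' optimal_tbwp("bipolar")$tbwp
#' @export
optimal_tbwp <- function(polarity = c("bipolar", "monopolar"),
                         inter_pulse_ms = 0.5, slab_thickness_mm = 48,
                         limits = hardware_limits()) {
  polarity <- match.arg(polarity)
  tau <- inter_pulse_ms * 1e-3
  dz <- slab_thickness_mm * 1e-3
  gmax <- limits$g_max * 1e-3
  f <- function(g) tbwp_lobe(g, polarity, tau, dz, limits)$tbwp
  ## coarse grid to bracket the maximum (the objective is zero on the
  ## infeasible high-amplitude plateau, which defeats golden-section
  ## search from the full interval), then local refinement
  g_grid <- seq(gmax / 400, gmax, length.out = 400)
  v_grid <- vapply(g_grid, f, numeric(1))
  if (all(v_grid <= 0)) stop("no feasible trapezoid for these timings")
  i <- which.max(v_grid)
  lo <- g_grid[max(1L, i - 1L)]; hi <- g_grid[min(length(g_grid), i + 1L)]
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)
  cand <- c(opt$maximum, g_grid[i], gmax)
  vals <- vapply(cand, f, numeric(1))
  g_best <- cand[which.max(vals)]
  det <- tbwp_lobe(g_best, polarity, tau, dz, limits)
  list(tbwp = det$tbwp, g_mT = g_best * 1e3, t_rf_ms = det$t_rf * 1e3,
       polarity = polarity)
}

#' Monopolar vs. bipolar optimal-TBWP comparison
#'
#' @param inter_pulse_ms vector of sub-pulse spacings to scan, ms.
#' @param slab_thickness_mm slab thickness, mm.
#' @param limits a [hardware_limits()].
#' @return data.frame with columns `inter_pulse_ms`, `tbwp_bipolar`,
#'   `tbwp_monopolar`, `reduction_pct` (100 x (1 - mono/bi)).
#' @export
tbwp_report <- function(inter_pulse_ms = 0.5, slab_thickness_mm = 48,
                        limits = hardware_limits()) {
  rows <- lapply(inter_pulse_ms, function(tau) {
    bi <- optimal_tbwp("bipolar", tau, slab_thickness_mm, limits)
    mo <- optimal_tbwp("monopolar", tau, slab_thickness_mm, limits)
    data.frame(inter_pulse_ms = tau, tbwp_bipolar = bi$tbwp,
               tbwp_monopolar = mo$tbwp,
               reduction_pct = 100 * (1 - mo$tbwp / bi$tbwp))
  })
  do.call(rbind, rows)
}

#' Binomial composite water-excitation pulse (single channel)
#'
#' Builds the classic binomial composite pulse: sub-pulses scaled by the
#' binomial coefficients (default 1-5-10-10-5-1, normalized to the target
#' flip), spaced so fat at `fat_offset` accrues pi radians between
#' sub-pulse centers (`inter_pulse = 1/(2 |fat_offset|)`), on either
#' alternating (bipolar) or same-polarity (monopolar, with fly-back
#' lobes) slab-selective trapezoids. The sub-pulse TBWP defaults to the
#' maximum feasible value from [optimal_tbwp()].
#'
#' @param coefficients binomial amplitude coefficients.
#' @param polarity `"bipolar"` or `"monopolar"`.
#' @param fat_offset fat resonance offset, Hz (default -1000 at 7 T).
#' @param slab_thickness_mm slab thickness, mm.
#' @param target_flip on-resonance composite flip, degrees.
#' @param limits a [hardware_limits()].
#' @param tbwp sub-pulse TBWP; NULL uses the optimal value.
#' @return a single-channel `waveform_set` with attributes
#'   `inter_pulse_ms` and `tbwp`.
#' @export
design_binomial <- function(coefficients = c(1, 5, 10, 10, 5, 1),
                            polarity = c("bipolar", "monopolar"),
                            fat_offset = -1000, slab_thickness_mm = 48,
                            target_flip = ernst_angle(),
                            limits = hardware_limits(), tbwp = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(all(coefficients > 0))
  n_sub <- length(coefficients)
  tau <- 1 / (2 * abs(fat_offset))                     # s
  opt <- optimal_tbwp(polarity, tau * 1e3, slab_thickness_mm, limits)
  if (is.null(tbwp)) tbwp <- opt$tbwp
  g <- opt$g_mT * 1e-3                                 # T/m
  t_rf <- opt$t_rf_ms * 1e-3                           # s
  s <- limits$slew_max
  t_ramp <- g / s
  lobe_area <- g * (t_rf + t_ramp)

  breaks <- 0; vals <- 0
  centers <- numeric(n_sub)
  for (l in seq_len(n_sub)) {
    sgn <- if (polarity == "bipolar" && l %% 2L == 0L) -1 else 1
    t0 <- (l - 1) * tau
    centers[l] <- t0 + tau / 2
    # center the lobe within its interval
    lobe_dur <- 2 * t_ramp + t_rf
    off <- t0 + (if (polarity == "bipolar") (tau - lobe_dur) / 2 else 0)
    breaks <- c(breaks, off + c(0, t_ramp, t_ramp + t_rf, lobe_dur))
    vals <- c(vals, 0, sgn * g * 1e3, sgn * g * 1e3, 0)
    if (polarity == "monopolar" && l < n_sub) {
      fb <- min_time_lobe(-lobe_area, limits)
      breaks <- c(breaks, off + lobe_dur + fb$breaks[-1])
      vals <- c(vals, fb$vals[-1])
    }
  }
  t_osc <- n_sub * tau
  last_sgn <- if (polarity == "bipolar" && n_sub %% 2L == 0L) -1 else 1
  rew <- min_time_lobe(-last_sgn * lobe_area / 2, limits)
  t_rew0 <- max(breaks)
  breaks <- c(breaks, t_rew0 + rew$breaks[-1])
  vals <- c(vals, rew$vals[-1])
  sg <- make_slab_gradient(breaks, vals, t_osc * 1e3, lobe_area,
                           centers * 1e3, limits)

  raster <- limits$raster_us
  n_osc <- round(t_osc / (raster * 1e-6))
  env <- sinc_subpulse(t_rf * 1e3, tbwp, raster)
  n_env <- length(env)
  area_env <- sum(env) * raster * 1e-6                 # s (unit peak)
  rf <- matrix(0i, n_osc, 1)
  wsum <- sum(coefficients)
  for (l in seq_len(n_sub)) {
    flip_l <- coefficients[l] / wsum * target_flip * pi / 180   # rad
    amp <- flip_l / (GAMMA * area_env * 1e-6)          # uT
    lobe_dur <- 2 * t_ramp + t_rf
    off <- (l - 1) * tau + (if (polarity == "bipolar") (tau - lobe_dur) / 2 else 0)
    ctr <- (off + t_ramp + t_rf / 2) / (raster * 1e-6)
    i0 <- round(ctr - n_env / 2)
    rf[i0 + seq_len(n_env), 1] <- amp * env
  }
  wf <- assemble_waveforms(sg, inplane_grad = NULL, rf = rf,
                           limits = limits, slab_axis = 3L,
                           rf_support = seq_len(n_osc))
  attr(wf, "inter_pulse_ms") <- tau * 1e3
  attr(wf, "tbwp") <- tbwp
  attr(wf, "polarity") <- polarity
  wf
}
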