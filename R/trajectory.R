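#' Gradient hardware limits
#'
#' @param g_max maximum gradient amplitude per axis, mT/m.
#' @param slew_max maximum slew rate per axis, T/m/s.
#' @param raster_us waveform raster (discretization step), microseconds.
#' @return object of class `hardware_limits`.
#' @export
hardware_limits <- function(g_max = 70, slew_max = 200, raster_us = 2) {
  stopifnot(g_max > 0, slew_max > 0, raster_us > 0)
  structure(list(g_max = g_max, slew_max = slew_max, raster_us = raster_us),
            class = "hardware_limits")
}

#' SPINS trajectory parameters
#'
#' Parameters of the spiral-nonselective (SPINS) k-space parameterization
#' `k(t) = (r sin(theta) cos(phi), r sin(theta) sin(phi), r cos(theta))`
#' with a logistic radial decay `r(t) = k_max / (1 + exp(alpha_s (t/t_p -
#' beta_s)))` and linear angular sweeps `theta = u t`, `phi = v t`. The
#' `_s` suffix distinguishes the radial shape constants from the
#' regularization weights of the design problem.
#'
#' @param k_max maximum k-space radius, rad/m.
#' @param alpha_s logistic decay steepness (unitless).
#' @param beta_s logistic midpoint as a fraction of `t_p` (unitless).
#' @param u polar angular rate, rad/ms.
#' @param v azimuthal angular rate, rad/ms.
#' @param t_p trajectory duration, ms.
#' @return object of class `spins_params`.
#' @export
spins_params <- function(k_max = 20, alpha_s = 10, beta_s = 0.5,
                         u = 8 * pi, v = 2 * pi, t_p = 3) {
  stopifnot(k_max > 0, t_p > 0)
  structure(list(k_max = k_max, alpha_s = alpha_s, beta_s = beta_s,
                 u = u, v = v, t_p = t_p), class = "spins_params")
}

## minimum-time gradient lobe of given zeroth moment (T*s/m) under limits;
## returns breakpoints (s) and values (mT/m): triangle, or trapezoid capped
## at g_max
min_time_lobe <- function(moment, limits) {
  s <- limits$slew_max
  gmax <- limits$g_max * 1e-3
  a <- abs(moment)
  if (a < .Machine$double.eps)
    return(list(breaks = numeric(0), vals = numeric(0), duration = 0))
  peak <- sqrt(a * s)
  if (peak <= gmax) {
    dur <- 2 * sqrt(a / s)
    br <- c(0, dur / 2, dur)
    vv <- c(0, sign(moment) * peak * 1e3, 0)
  } else {
    t_r <- gmax / s
    t_pl <- a / gmax - t_r
    dur <- 2 * t_r + t_pl
    br <- c(0, t_r, t_r + t_pl, dur)
    vv <- c(0, sign(moment) * limits$g_max, sign(moment) * limits$g_max, 0)
  }
  list(breaks = br, vals = vv, duration = dur)
}

#' Bipolar trapezoidal slab-selective gradient with rewinder
#'
#' Builds `n_pairs` pairs of alternating-polarity trapezoid lobes, each
#' lobe filling half an oscillation period (maximum-slew ramps, constant
#' plateau), followed by a minimum-time rewinder lobe of half the lobe
#' area and opposite polarity to the final lobe. The half-area rewinder
#' centers the slab-axis excitation k-space excursion about zero, so the
#' slab-axis k-space value seen at the center of every lobe is refocused
#' to zero at the end of the pulse (the usual slice-refocusing condition).
#'
#' @param n_pairs number of bipolar pairs (default 3).
#' @param period_ms oscillation period in ms (default 1; each lobe lasts
#'   `period_ms / 2`).
#' @param plateau plateau amplitude, mT/m.
#' @param limits a [hardware_limits()].
#' @return object of class `slab_gradient`: piecewise-linear breakpoints
#'   (`breaks_s`, `vals` in mT/m), oscillation window `t_osc_ms`, total
#'   duration `t_total_ms`, per-lobe area (T*s/m) and lobe centers (ms).
#' @examples
#' sg <- bipolar_slab_gradient()
#' sg$t_total_ms  # about 3.2 ms
#' @export
bipolar_slab_gradient <- function(n_pairs = 3L, period_ms = 1,
                                  plateau = 25, limits = hardware_limits()) {
  stopifnot(n_pairs >= 1, period_ms > 0, plateau > 0)
  if (plateau > limits$g_max) stop("infeasible trapezoid: plateau above g_max")
  half <- period_ms / 2 * 1e-3                      # lobe duration, s
  t_r <- plateau * 1e-3 / limits$slew_max           # ramp time, s
  if (2 * t_r >= half)
    stop("infeasible trapezoid: ramps do not fit in half period")
  lobe_area <- plateau * 1e-3 * (half - t_r)        # T*s/m
  breaks <- 0; vals <- 0
  for (l in seq_len(2L * n_pairs)) {
    sgn <- if (l %% 2L == 1L) 1 else -1
    t0 <- (l - 1) * half
    breaks <- c(breaks, t0 + t_r, t0 + half - t_r, t0 + half)
    vals <- c(vals, sgn * plateau, sgn * plateau, 0)
  }
  t_osc <- 2 * n_pairs * half
  last_sign <- if ((2L * n_pairs) %% 2L == 1L) 1 else -1
  rew <- min_time_lobe(-last_sign * lobe_area / 2, limits)
  breaks <- c(breaks, t_osc + rew$breaks[-1])
  vals <- c(vals, rew$vals[-1])
  structure(list(
    breaks_s = breaks, vals = vals,
    plateau = plateau, n_pairs = as.integer(n_pairs),
    period_ms = period_ms, ramp_ms = t_r * 1e3,
    t_osc_ms = t_osc * 1e3, t_total_ms = (t_osc + rew$duration) * 1e3,
    lobe_area = lobe_area,
    lobe_centers_ms = ((seq_len(2L * n_pairs) - 0.5) * half) * 1e3,
    limits = limits), class = "slab_gradient")
}

#' Sample a piecewise-linear gradient at raster midpoints
#'
#' @param breaks_s breakpoint times, s.
#' @param vals gradient values at the breakpoints, mT/m.
#' @param raster_us raster, microseconds.
#' @param n_samples optional sample count (default covers the breakpoints).
#' @return numeric vector of mT/m values at interval midpoints.
#' @export
sample_gradient <- function(breaks_s, vals, raster_us, n_samples = NULL) {
  dt <- raster_us * 1e-6
  keep <- !duplicated(breaks_s)
  breaks_s <- breaks_s[keep]; vals <- vals[keep]
  if (is.null(n_samples)) n_samples <- ceiling(max(breaks_s) / dt - 1e-9)
  t_mid <- (seq_len(n_samples) - 0.5) * dt
  out <- approx(breaks_s, vals, xout = t_mid, yleft = 0, yright = 0,
                rule = 2)$y
  out[t_mid > max(breaks_s)] <- 0
  out
}

#' SPINS-like 2D in-plane k-space trajectory
#'
#' Evaluates the 3D spherical SPINS formula and returns its two transverse
#' components, which serve as the in-plane trajectory played concurrently
#' with the bipolar slab gradient. Samples are returned at raster
#' boundaries `t = 0, dt, ..., t_p`, ready for [k_to_gradient()].
#'
#' @param p a [spins_params()].
#' @param raster_us raster, microseconds.
#' @return (n+1) x 2 matrix of k-space samples, rad/m, with attribute
#'   `times_ms`.
#' @export
spins_inplane_trajectory <- function(p = spins_params(), raster_us = 2) {
  n <- round(p$t_p * 1e3 / raster_us)
  t_ms <- (0:n) * raster_us * 1e-3
  r <- p$k_max / (1 + exp(p$alpha_s * (t_ms / p$t_p - p$beta_s)))
  th <- p$u * t_ms
  ph <- p$v * t_ms
  k <- cbind(r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  attr(k, "times_ms") <- t_ms
  k
}

#' Radial component of the SPINS trajectory
#'
#' @param t_ms time, ms.
#' @param p a [spins_params()].
#' @return k-space radius, rad/m.
#' @export
spins_radius <- function(t_ms, p = spins_params()) {
  p$k_max / (1 + exp(p$alpha_s * (t_ms / p$t_p - p$beta_s)))
}

#' Convert a k-space trajectory to gradient waveforms
#'
#' Uses the excitation k-space convention `k(t) = -gamma int_t^T G(s)
#' ds`, under which the trajectory always ends at the k-space origin. The
#' gradient is the forward difference of the prescribed samples; if the
#' prescribed trajectory does not end at zero, a minimum-time rewinder is
#' appended per axis so the achieved excitation k-space equals the
#' prescription exactly over the main portion. If the finite-difference
#' gradient violates the limits, the trajectory is uniformly time-dilated
#' (re-sampled onto a longer raster grid) by the smallest integer factor
#' that restores feasibility.
#'
#' @param k (n+1) x d matrix of k samples (rad/m) at raster boundaries.
#' @param raster_us raster, microseconds.
#' @param limits a [hardware_limits()].
#' @param gamma gyromagnetic ratio, rad/s/T.
#' @param max_dilation largest allowed dilation factor before erroring.
#' @return list with `grad` (m x d, mT/m, raster midpoint samples),
#'   `n_main` (samples before the rewinder), `raster_us`, `dilation`.
#' @export
k_to_gradient <- function(k, raster_us, limits = hardware_limits(),
                          gamma = GAMMA, max_dilation = 8L,
                          rewind = TRUE) {
  k <- as.matrix(k)
  dt <- raster_us * 1e-6
  for (dil in seq_len(max_dilation)) {
    if (dil > 1L) {
      n_new <- (nrow(k) - 1L) * dil
      ti <- seq(0, 1, length.out = n_new + 1L)
      t0 <- seq(0, 1, length.out = nrow(k))
      k_use <- apply(k, 2, function(col) approx(t0, col, xout = ti)$y)
    } else k_use <- k
    g <- apply(k_use, 2, diff) / (gamma * dt) * 1e3   # mT/m
    g <- matrix(g, ncol = ncol(k))
    ok <- max(abs(g)) <= limits$g_max + 1e-9 &&
      max(abs(apply(g, 2, diff))) / (raster_us * 1e-3) <= limits$slew_max + 1e-9
    if (ok) break
    if (dil == max_dilation) stop("infeasible trajectory after dilation bound")
  }
  n_main <- nrow(g)
  k_end <- k[nrow(k), ]
  if (rewind && any(abs(k_end) > 1e-12)) {
    moments <- -k_end / gamma                        # T*s/m per axis
    lobes <- lapply(moments, min_time_lobe, limits = limits)
    dur <- max(vapply(lobes, `[[`, numeric(1), "duration"))
    if (dur > 0) {
      n_rew <- ceiling(dur / dt - 1e-9)
      rew <- vapply(seq_along(lobes), function(a) {
        lb <- lobes[[a]]
        if (length(lb$breaks) == 0) return(numeric(n_rew))
        # stretch each axis lobe to the common duration, preserving area
        scale_t <- dur / lb$duration
        sample_gradient(lb$breaks * scale_t, lb$vals / scale_t, raster_us,
                        n_rew)
      }, numeric(ceiling(dur / dt - 1e-9)))
      g <- rbind(g, matrix(rew, ncol = ncol(g)))
    }
  }
  list(grad = g, n_main = n_main, raster_us = raster_us, dilation = dil)
}

#' Convert gradient waveforms to the excitation k-space trajectory
#'
#' Inverse of [k_to_gradient()] under the convention
#' `k(t) = -gamma int_t^T G(s) ds`; the returned trajectory ends at zero
#' by construction.
#'
#' @param grad m x d matrix of gradient samples, mT/m, at raster midpoints.
#' @param raster_us raster, microseconds.
#' @param gamma gyromagnetic ratio, rad/s/T.
#' @return (m+1) x d matrix of k samples (rad/m) at raster boundaries.
#' @export
gradient_to_k <- function(grad, raster_us, gamma = GAMMA) {
  grad <- as.matrix(grad)
  dt <- raster_us * 1e-6
  inc <- grad * 1e-3 * gamma * dt       # rad/m per interval
  k <- apply(inc, 2, function(col) c(0, cumsum(col)))
  k <- matrix(k, ncol = ncol(grad))
  sweep(k, 2, k[nrow(k), ], "-")
}

#' Assemble a validated multi-channel waveform set
#'
#' Merges the slab-selective gradient, the in-plane gradients and the
#' per-channel RF into one waveform set on a common raster. RF support
#' covers exactly the slab-gradient oscillation window; the rewinder
#' portion carries no RF. In-plane gradients (including any in-plane
#' rewinder) may extend into the slab-rewinder window; the total length is
#' the longer of the two.
#'
#' @param slab_grad a [bipolar_slab_gradient()] result.
#' @param inplane_grad m x 2 matrix of in-plane gradients (mT/m) from
#'   [k_to_gradient()], or NULL for none.
#' @param rf complex matrix (n_support x n_channels), microtesla; or NULL
#'   for zero RF (returns the gradient-only set with 1 channel).
#' @param limits a [hardware_limits()] (raster taken from here).
#' @param slab_axis gradient axis (1..3) carrying the slab gradient.
#' @param rf_support optional explicit support indices; default is the
#'   full oscillation window.
#' @return object of class `waveform_set`.
#' @export
assemble_waveforms <- function(slab_grad, inplane_grad = NULL, rf = NULL,
                               limits = hardware_limits(), slab_axis = 3L,
                               rf_support = NULL) {
  raster_us <- limits$raster_us
  gz <- sample_gradient(slab_grad$breaks_s, slab_grad$vals, raster_us)
  n_osc <- round(slab_grad$t_osc_ms * 1e3 / raster_us)
  n <- length(gz)
  if (!is.null(inplane_grad)) {
    inplane_grad <- as.matrix(inplane_grad)
    if (nrow(inplane_grad) < n_osc)
      stop("assembly error: in-plane gradient shorter than the RF window")
    n <- max(n, nrow(inplane_grad))
  }
  grad <- matrix(0, n, 3)
  grad[seq_along(gz), slab_axis] <- gz
  if (!is.null(inplane_grad))
    grad[seq_len(nrow(inplane_grad)), setdiff(1:3, slab_axis)] <- inplane_grad
  if (is.null(rf_support)) rf_support <- seq_len(n_osc)
  if (max(rf_support) > n) {       # gradient ended before the RF window
    grad <- rbind(grad, matrix(0, max(rf_support) - n, 3))
    n <- max(rf_support)
  }
  n_ch <- if (is.null(rf)) 1L else ncol(rf)
  rf_full <- matrix(0i, n, n_ch)
  if (!is.null(rf)) {
    if (nrow(rf) != length(rf_support))
      stop("assembly error: RF length does not match the support window")
    rf_full[rf_support, ] <- rf
  }
  wf <- structure(list(
    rf = rf_full, grad = grad, raster_us = raster_us,
    rf_support = rf_support, t_total_ms = n * raster_us * 1e-3,
    slab_axis = as.integer(slab_axis), limits = limits,
    slab_grad = slab_grad), class = "waveform_set")
  validate_waveform(wf)
  wf
}

#' Validate a waveform set against hardware limits
#'
#' Checks per-axis gradient amplitude and sample-to-sample slew rate, and
#' that RF is zero outside its support window.
#'
#' @param wf a `waveform_set`.
#' @param limits a [hardware_limits()]; defaults to the set's own.
#' @return `wf`, invisibly; errors on violation.
#' @export
validate_waveform <- function(wf, limits = wf$limits) {
  tol <- 1e-6
  if (max(abs(wf$grad)) > limits$g_max + tol)
    stop(sprintf("gradient amplitude %.3f mT/m exceeds limit %.1f",
                 max(abs(wf$grad)), limits$g_max))
  dg <- abs(apply(wf$grad, 2, diff)) / (wf$raster_us * 1e-3)
  if (max(dg) > limits$slew_max + tol)
    stop(sprintf("slew rate %.1f T/m/s exceeds limit %.1f",
                 max(dg), limits$slew_max))
  outside <- setdiff(seq_len(nrow(wf$rf)), wf$rf_support)
  if (length(outside) && any(wf$rf[outside, ] != 0))
    stop("RF nonzero outside its support window")
  invisible(wf)
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf(
    "waveform_set: %d channels, %d samples at %g us (%.3f ms), RF support %d samples\n",
    ncol(x$rf), nrow(x$grad), x$raster_us, x$t_total_ms,
    length(x$rf_support)))
  invisible(x)
}

#' Excitation k-space of a waveform set
#'
#' @param wf a `waveform_set`.
#' @param gamma gyromagnetic ratio, rad/s/T.
#' @return (n+1) x 3 matrix, rad/m.
#' @export
waveform_k <- function(wf, gamma = GAMMA) {
  gradient_to_k(wf$grad, wf$raster_us, gamma)
}

#' Export a waveform set to a tabular text file
#'
#' Columns: time (us), Gx, Gy, Gz (mT/m), then per-channel RF real and
#' imaginary parts (uT). A comment header carries the raster, RF support
#' window and slab axis so [read_waveform()] can reconstruct the set.
#' @param wf a `waveform_set`.
#' @param path output path (TSV).
#' @export
write_waveform <- function(wf, path) {
  n <- nrow(wf$grad)
  df <- data.frame(time_us = (seq_len(n) - 0.5) * wf$raster_us,
                   gx = wf$grad[, 1], gy = wf$grad[, 2], gz = wf$grad[, 3])
  for (c in seq_len(ncol(wf$rf))) {
    df[[sprintf("rf%d_re", c)]] <- Re(wf$rf[, c])
    df[[sprintf("rf%d_im", c)]] <- Im(wf$rf[, c])
  }
  hdr <- c(sprintf("# raster_us %g", wf$raster_us),
           sprintf("# rf_support %d %d", min(wf$rf_support),
                   max(wf$rf_support)),
           sprintf("# slab_axis %d", wf$slab_axis),
           sprintf("# g_max %g slew_max %g", wf$limits$g_max,
                   wf$limits$slew_max))
  writeLines(hdr, path)
  suppressWarnings(write.table(df, path, sep = "\t", row.names = FALSE,
                               quote = FALSE, append = TRUE))
  invisible(path)
}

#' Read a waveform set written by [write_waveform()]
#'
#' @param path TSV path.
#' @return a `waveform_set`.
#' @export
read_waveform <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10), value = TRUE)
  gv <- function(key) suppressWarnings(as.numeric(strsplit(
    sub(paste0("^# ", key, " "), "", grep(paste0("^# ", key), hdr,
                                          value = TRUE)), " ")[[1]]))
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  n_ch <- (ncol(tab) - 4L) %/% 2L
  rf <- matrix(0i, nrow(tab), n_ch)
  for (c in seq_len(n_ch))
    rf[, c] <- complex(real = tab[[sprintf("rf%d_re", c)]],
                       imaginary = tab[[sprintf("rf%d_im", c)]])
  sup <- gv("rf_support")
  lim <- gv("g_max")
  structure(list(rf = rf, grad = as.matrix(tab[, c("gx", "gy", "gz")]),
                 raster_us = gv("raster_us"),
                 rf_support = seq.int(sup[1], sup[2]),
                 t_total_ms = nrow(tab) * gv("raster_us") * 1e-3,
                 slab_axis = as.integer(gv("slab_axis")),
                 limits = hardware_limits(lim[1], lim[3],
                                          gv("raster_us"))),
            class = "waveform_set")
}
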