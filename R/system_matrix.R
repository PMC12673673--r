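#' Small-tip-angle spatial-domain system matrix
#'
#' Builds the complex matrix mapping concatenated per-channel RF samples
#' (microtesla) to transverse excitation (degrees of flip) at sampled
#' spatial-spectral points. The entry for spatial sample r (off-resonance
#' `db0(r)` Hz), spectral frequency f, channel c and time sample j is
#'
#'   `i * gamma * dt * b1_c(r) * exp(i 2 pi (db0(r)+f) (t_j - T)) *
#'    exp(i k(t_j) . r)`
#'
#' with `k(t)` the excitation k-space of the full gradient waveform
#' (including the rewinder) and T the end of the waveform. Rows are
#' ordered frequency-major (all samples at the first frequency, then the
#' next); columns are grouped by channel, time samples within a channel.
#'
#' @param samples list with `pos` (n x 3 mm), `b1` (n x n_channels
#'   complex), `db0` (n, Hz), e.g. from [downsample_region()].
#' @param freqs spectral frequencies, Hz.
#' @param wf a `waveform_set`.
#' @param gamma gyromagnetic ratio, rad/s/T.
#' @return complex matrix (n * length(freqs)) x (n_channels *
#'   n_rf_samples), degrees per microtesla, with attribute `meta` (a
#'   data.frame of row positions and frequencies).
#' @export
sta_matrix <- function(samples, freqs, wf, gamma = GAMMA) {
  if (length(freqs) == 0L) stop("empty frequency list")
  n <- nrow(samples$pos)
  n_ch <- ncol(samples$b1)
  dt <- wf$raster_us * 1e-6
  sup <- wf$rf_support
  n_t <- length(sup)
  n_tot <- nrow(wf$grad)

  ## excitation k at RF sample midpoints (rad/m): k(t) = -gamma int_t^T G
  k_bound <- gradient_to_k(wf$grad, wf$raster_us, gamma)      # (n_tot+1) x 3
  k_mid <- (k_bound[sup, , drop = FALSE] +
              k_bound[sup + 1L, , drop = FALSE]) / 2
  t_mid <- (sup - 0.5) * dt                                   # s
  t_end <- n_tot * dt

  pos_m <- samples$pos * 1e-3
  spatial <- exp(1i * (pos_m %*% t(k_mid)))                   # n x n_t
  scale <- 1i * gamma * 1e-6 * dt * 180 / pi                  # deg per uT

  blocks <- vector("list", length(freqs))
  for (fi in seq_along(freqs)) {
    ph_f <- exp(2i * pi * outer(samples$db0 + freqs[fi], t_mid - t_end))
    core <- spatial * ph_f                                    # n x n_t
    row_block <- matrix(0i, n, n_ch * n_t)
    for (c in seq_len(n_ch))
      row_block[, (c - 1L) * n_t + seq_len(n_t)] <-
        (scale * samples$b1[, c]) * core
    blocks[[fi]] <- row_block
  }
  A <- do.call(rbind, blocks)
  attr(A, "meta") <- data.frame(
    freq = rep(freqs, each = n),
    x = rep(samples$pos[, 1], length(freqs)),
    y = rep(samples$pos[, 2], length(freqs)),
    z = rep(samples$pos[, 3], length(freqs)))
  attr(A, "n_channels") <- n_ch
  attr(A, "n_t") <- n_t
  A
}

#' Build the four-region spatial-spectral design problem
#'
#' Constructs the three system matrices of the regularized
#' magnitude-least-squares problem: `A_iw` (inside-slab water at the
#' water frequencies, down-sampled in-plane only), `A_ow` (out-of-slab
#' water), and `A_f` (fat stopband over the whole brain at the five fat
#' frequencies), the latter two down-sampled both in-plane and
#' through-plane. Don't-care (transition-band) voxels appear in no
#' matrix.
#'
#' @param cal a `calibration_set`.
#' @param regions a [define_regions()] result.
#' @param wf a `waveform_set` providing the trajectory and RF raster.
#' @param alpha0 target in-slab flip angle, degrees.
#' @param lambda1 weight on the out-of-slab water term (default 2).
#' @param lambda2 weight on the fat term (default 8).
#' @param beta_reg Tikhonov weight on integrated RF power (default 2000).
#'   The power term is `beta_reg * sum(|x_j|^2) * dt` with `dt` the RF
#'   raster in seconds, i.e. `beta_reg` weights integrated RF power
#'   (microtesla^2 * s) against squared-degree residuals; this makes the
#'   regularization independent of the raster choice.
#' @param iw_inplane,iw_throughplane in-slab down-sampling (mm); through-
#'   plane defaults to native resolution.
#' @param sb_inplane,sb_throughplane stopband (out-of-slab water and fat)
#'   down-sampling (mm).
#' @return object of class `design_problem`.
#' @export
build_design_problem <- function(cal, regions, wf, alpha0 = ernst_angle(),
                                 lambda1 = 2, lambda2 = 8, beta_reg = 2000,
                                 iw_inplane = 6,
                                 iw_throughplane = cal$grid$voxel_size[cal$grid$slab_axis],
                                 sb_inplane = 18, sb_throughplane = 9) {
  s_iw <- downsample_region(cal, regions$mask_inslab_water,
                            iw_inplane, iw_throughplane)
  s_ow <- downsample_region(cal, regions$mask_outslab_water,
                            sb_inplane, sb_throughplane)
  s_f <- downsample_region(cal, regions$mask_fat,
                           sb_inplane, sb_throughplane)
  if (nrow(s_iw$pos) == 0L) stop("inside-slab water region is empty")
  if (nrow(s_ow$pos) == 0L) stop("out-of-slab water region is empty")
  if (nrow(s_f$pos) == 0L) stop("fat region is empty")
  A_iw <- sta_matrix(s_iw, regions$water_freqs, wf)
  A_ow <- sta_matrix(s_ow, regions$water_freqs, wf)
  A_f <- sta_matrix(s_f, regions$fat_freqs, wf)
  structure(list(
    A_iw = A_iw, A_ow = A_ow, A_f = A_f,
    alpha0 = alpha0, lambda1 = lambda1, lambda2 = lambda2,
    beta_reg = beta_reg, power_scale = wf$raster_us * 1e-6,
    n_channels = attr(A_iw, "n_channels"), n_t = attr(A_iw, "n_t"),
    wf = wf), class = "design_problem")
}

#' @export
print.design_problem <- function(x, ...) {
  cat(sprintf(
    paste0("design_problem: A_iw %d x %d, A_ow %d rows, A_f %d rows; ",
           "alpha0 %.2f deg, lambda1 %g, lambda2 %g, beta %g\n"),
    nrow(x$A_iw), ncol(x$A_iw), nrow(x$A_ow), nrow(x$A_f),
    x$alpha0, x$lambda1, x$lambda2, x$beta_reg))
  invisible(x)
}

#' Insert a solved RF vector into a waveform set
#'
#' Reshapes the concatenated channel-major RF solution (microtesla per
#' sample) onto the RF support of the waveform set.
#'
#' @param wf a `waveform_set` (defines the raster and support).
#' @param x complex vector of length `n_channels * n_t`.
#' @param n_channels number of channels.
#' @return a `waveform_set` with the RF filled in.
#' @export
set_rf <- function(wf, x, n_channels) {
  n_t <- length(wf$rf_support)
  stopifnot(length(x) == n_channels * n_t)
  rf <- matrix(x, nrow = n_t, ncol = n_channels)
  out <- wf
  out$rf <- matrix(0i, nrow(wf$grad), n_channels)
  out$rf[wf$rf_support, ] <- rf
  validate_waveform(out)
  out
}
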