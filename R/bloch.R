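#' Bloch-simulate a waveform set over space and frequency
#'
#' Hard-pulse integration of the Bloch equation (relaxation neglected) at
#' the waveform raster, starting from equilibrium magnetization. At each
#' step the magnetization is rotated about the instantaneous effective
#' field: transverse components `sum_c b1_c(r) rf_c(t)`, longitudinal
#' component `(db0(r) + f) + gamma_bar G(t) . r` expressed in Hz. The
#' flip angle is `atan2(|Mxy|, Mz)` at the end of the waveform.
#'
#' @param wf a `waveform_set`.
#' @param cal a `calibration_set` (native maps), or NULL when `positions`
#'   supplies explicit samples.
#' @param freqs spectral frequency offsets to simulate, Hz.
#' @param positions NULL (all brain-mask voxels), a logical volume, or a
#'   sample list with `pos` (n x 3 mm), `b1` (n x n_channels), `db0` (n)
#'   as produced by [downsample_region()].
#' @param gamma gyromagnetic ratio, rad/s/T.
#' @return object of class `simulation_result`: `flip` (n x n_freq,
#'   degrees), `mz`, `mxy` (complex transverse magnetization), `freqs`,
#'   `pos` (mm), `vox` (linear voxel indices or NA), `grid`.
#' @export
bloch_simulate <- function(wf, cal, freqs = 0, positions = NULL,
                           gamma = GAMMA) {
  if (is.list(positions) && !is.null(positions$pos)) {
    pos <- positions$pos; b1 <- positions$b1; db0 <- positions$db0
    vox <- rep(NA_integer_, nrow(pos))
    grid <- if (!is.null(cal)) cal$grid else NULL
  } else {
    mask <- if (is.null(positions)) cal$mask_brain else
      array(as.logical(positions), dim = cal$grid$shape)
    vox <- which(mask)
    idx <- which(mask, arr.ind = TRUE)
    pos <- grid_coords(cal$grid, idx)
    nvox <- prod(cal$grid$shape)
    b1 <- vapply(seq_len(cal$n_channels),
                 function(c) cal$b1[vox + (c - 1) * nvox],
                 complex(length(vox)))
    b1 <- matrix(b1, ncol = cal$n_channels)
    db0 <- cal$db0[vox]
    grid <- cal$grid
  }
  dt <- wf$raster_us * 1e-6
  flip <- matrix(NA_real_, nrow(pos), length(freqs))
  mz <- matrix(NA_real_, nrow(pos), length(freqs))
  mxy <- matrix(NA_complex_, nrow(pos), length(freqs))
  for (fi in seq_along(freqs)) {
    M <- bloch_run(b1, wf$rf, wf$grad, pos * 1e-3, db0 + freqs[fi],
                   dt, gamma)
    flip[, fi] <- atan2(sqrt(M[, 1]^2 + M[, 2]^2), M[, 3]) * 180 / pi
    mz[, fi] <- M[, 3]
    mxy[, fi] <- complex(real = M[, 1], imaginary = M[, 2])
  }
  structure(list(flip = flip, mz = mz, mxy = mxy, freqs = freqs, pos = pos,
                 vox = vox, grid = grid), class = "simulation_result")
}

#' Flip-angle volume at one simulated frequency
#'
#' @param result a `simulation_result` simulated on grid voxels.
#' @param freq frequency (must be one of `result$freqs`).
#' @return 3D array of flip angles (degrees), NA outside the simulated
#'   voxels.
#' @export
flip_volume <- function(result, freq = 0) {
  fi <- match(freq, result$freqs)
  if (is.na(fi)) stop("frequency not simulated")
  if (anyNA(result$vox)) stop("result was not simulated on grid voxels")
  vol <- array(NA_real_, dim = result$grid$shape)
  vol[result$vox] <- result$flip[, fi]
  vol
}

#' Full width at half maximum of a 1D profile
#'
#' The plateau level is the median of the samples within 80% of the
#' profile maximum; the FWHM is measured between the two half-level
#' crossings found by linear interpolation on an (optionally) upsampled
#' profile.
#'
#' @param position sample positions, mm (ascending).
#' @param value profile values.
#' @param interp_factor linear upsampling factor before crossing search.
#' @return list with `fwhm` (mm, NA if undefined), `left`, `right`,
#'   `level`, `undefined` (flag).
#' @export
profile_fwhm <- function(position, value, interp_factor = 10) {
  ord <- order(position)
  position <- position[ord]; value <- value[ord]
  if (interp_factor > 1 && length(position) > 1) {
    fine <- seq(min(position), max(position),
                length.out = (length(position) - 1L) * interp_factor + 1L)
    value <- approx(position, value, xout = fine)$y
    position <- fine
  }
  pk <- max(value)
  level <- median(value[value >= 0.8 * pk])
  half <- level / 2
  above <- value >= half
  if (all(above) || !any(above))
    return(list(fwhm = NA_real_, left = NA_real_, right = NA_real_,
                level = level, undefined = TRUE))
  i_pk <- which.max(value)
  cross_at <- function(i0, i1) {
    # linear interpolation of the half crossing between samples i0, i1
    position[i0] + (half - value[i0]) / (value[i1] - value[i0]) *
      (position[i1] - position[i0])
  }
  left <- NA_real_; right <- NA_real_
  i <- i_pk
  while (i > 1L) { if (!above[i - 1L]) { left <- cross_at(i - 1L, i); break }; i <- i - 1L }
  i <- i_pk
  n <- length(value)
  while (i < n) { if (!above[i + 1L]) { right <- cross_at(i + 1L, i); break }; i <- i + 1L }
  if (is.na(left) || is.na(right))
    return(list(fwhm = NA_real_, left = left, right = right,
                level = level, undefined = TRUE))
  list(fwhm = right - left, left = left, right = right, level = level,
       undefined = FALSE)
}

#' Slab profile along the slab axis with FWHM
#'
#' Traces flip angle along a line parallel to the slab axis through the
#' in-plane center (or a specified in-plane location), and measures the
#' effective slab thickness as the FWHM of the profile.
#'
#' @param result a `simulation_result` on grid voxels.
#' @param freq frequency to trace (default 0 Hz, water).
#' @param inplane_index optional length-2 integer vector giving the voxel
#'   index along the two non-slab axes; default is the in-plane center.
#' @param interp_factor upsampling for the FWHM search.
#' @return list with `position` (mm), `flip` (degrees), `fwhm` (mm),
#'   `undefined` flag.
#' @export
slab_profile <- function(result, freq = 0, inplane_index = NULL,
                         interp_factor = 10) {
  grid <- result$grid
  ax <- grid$slab_axis
  others <- setdiff(1:3, ax)
  if (is.null(inplane_index))
    inplane_index <- vapply(others, function(a)
      which.min(abs(grid_axis_coords(grid, a))), integer(1))
  fi <- match(freq, result$freqs)
  if (is.na(fi)) stop("frequency not simulated")
  idx <- which(array(TRUE, grid$shape), arr.ind = TRUE)[result$vox, ,
                                                        drop = FALSE]
  sel <- idx[, others[1]] == inplane_index[1] &
    idx[, others[2]] == inplane_index[2]
  if (!any(sel)) stop("centerline contains no simulated voxels")
  pos <- result$pos[sel, ax]
  flip <- result$flip[sel, fi]
  ord <- order(pos)
  fw <- profile_fwhm(pos[ord], flip[ord], interp_factor)
  list(position = pos[ord], flip = flip[ord], fwhm = fw$fwhm,
       level = fw$level, undefined = fw$undefined)
}

#' Spatial-spectral response pattern of a pulse
#'
#' Simulates the pulse over a sweep of frequency offsets, averages the
#' response intensity (`sin(flip)`, the small-signal GRE proxy) across
#' three lines traversing the slab direction at the in-plane center, and
#' interpolates along the frequency axis to a denser step.
#'
#' @param wf a `waveform_set`.
#' @param cal a `calibration_set` (e.g. a uniform spherical phantom).
#' @param freq_range sweep range, Hz (default -1300 to 300).
#' @param step native sweep step, Hz (default 100).
#' @param interp_step interpolated frequency resolution, Hz (default 10).
#' @param n_lines number of averaged centerlines (default 3).
#' @return list with `response` (n_z x n_freq_interp intensity matrix),
#'   `z_mm`, `freqs` (interpolated), `freqs_native`, `intensity_native`
#'   (intensity at the native sweep offsets).
#' @export
spsp_response <- function(wf, cal, freq_range = c(-1300, 300), step = 100,
                          interp_step = 10, n_lines = 3L) {
  if (interp_step > step) stop("interp_step must not exceed the sweep step")
  freqs <- seq(freq_range[1], freq_range[2], by = step)
  grid <- cal$grid
  ax <- grid$slab_axis
  others <- setdiff(1:3, ax)
  c1 <- which.min(abs(grid_axis_coords(grid, others[1])))
  c2 <- which.min(abs(grid_axis_coords(grid, others[2])))
  offs <- seq_len(n_lines) - (n_lines + 1L) %/% 2L
  line_mask <- array(FALSE, grid$shape)
  idx <- which(cal$mask_brain, arr.ind = TRUE)
  keep <- idx[, others[1]] %in% (c1 + offs) & idx[, others[2]] == c2
  line_mask[idx[keep, , drop = FALSE]] <- TRUE
  if (!any(line_mask)) stop("centerlines contain no in-mask voxels")
  sim <- bloch_simulate(wf, cal, freqs, positions = line_mask)
  zpos <- sim$pos[, ax]
  z_mm <- sort(unique(zpos))
  native <- matrix(NA_real_, length(z_mm), length(freqs))
  for (zi in seq_along(z_mm)) {
    sel <- zpos == z_mm[zi]
    native[zi, ] <- colMeans(sin(sim$flip[sel, , drop = FALSE] * pi / 180))
  }
  f_out <- seq(freq_range[1], freq_range[2], by = interp_step)
  resp <- t(apply(native, 1, function(row)
    approx(freqs, row, xout = f_out)$y))
  list(response = resp, z_mm = z_mm, freqs = f_out, freqs_native = freqs,
       intensity_native = native)
}

## upsample a waveform set by an integer factor (sample replication:
## preserves the hard-pulse physics exactly)
upsample_waveform <- function(wf, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(wf)
  rep_idx <- rep(seq_len(nrow(wf$grad)), each = factor)
  out <- wf
  out$grad <- wf$grad[rep_idx, , drop = FALSE]
  out$rf <- wf$rf[rep_idx, , drop = FALSE]
  out$raster_us <- wf$raster_us / factor
  out$rf_support <- which(rep(seq_len(nrow(wf$grad)) %in% wf$rf_support,
                              each = factor))
  out
}

## shift gradients by an integer number of samples relative to RF
## (positive delay = gradients late), padding with zeros
shift_gradients <- function(wf, n_shift) {
  if (n_shift == 0L) return(wf)
  n <- nrow(wf$grad)
  a <- abs(n_shift)
  out <- wf
  pad_g <- matrix(0, a, 3)
  pad_rf <- matrix(0i, a, ncol(wf$rf))
  if (n_shift > 0L) {
    out$grad <- rbind(pad_g, wf$grad)
    out$rf <- rbind(wf$rf, pad_rf)
  } else {
    out$grad <- rbind(wf$grad, pad_g)
    out$rf <- rbind(pad_rf, wf$rf)
    out$rf_support <- wf$rf_support + a
  }
  out$t_total_ms <- nrow(out$grad) * out$raster_us * 1e-3
  out
}

#' Gradient-delay sensitivity scan
#'
#' Re-simulates the pulse with the gradient waveforms time-shifted
#' relative to the RF by each requested delay, and reports water and fat
#' RMSE per delay. Waveforms are resampled to a 1-microsecond raster (by
#' sample replication) so odd-microsecond delays are realizable; the
#' delay-zero row is the reference simulated on the same resampled
#' raster.
#'
#' @param wf a `waveform_set`.
#' @param cal a `calibration_set`.
#' @param regions a [define_regions()] result.
#' @param alpha0 in-slab water target flip, degrees.
#' @param delays_us integer delays, microseconds (default -5..5).
#' @param eval_res optional evaluation-grid resolution (mm) to speed up
#'   the Bloch evaluation; NULL evaluates at native resolution.
#' @return data.frame with `delay_us`, `rmse_water`, `rmse_fat` (degrees).
#' @export
delay_scan <- function(wf, cal, regions, alpha0 = ernst_angle(),
                       delays_us = -5:5, eval_res = NULL) {
  res <- if (is.null(eval_res)) cal$grid$voxel_size[1] else eval_res
  s_iw <- downsample_region(cal, regions$mask_inslab_water, res, res)
  s_ow <- downsample_region(cal, regions$mask_outslab_water, res, res)
  s_f <- downsample_region(cal, regions$mask_fat, res, res)
  base_raster <- 1
  factor <- as.integer(round(wf$raster_us / base_raster))
  wf1 <- upsample_waveform(wf, max(1L, factor))
  shifts <- as.integer(round(delays_us / wf1$raster_us))
  out <- data.frame(delay_us = delays_us, rmse_water = NA_real_,
                    rmse_fat = NA_real_)
  for (i in seq_along(shifts)) {
    wfd <- shift_gradients(wf1, shifts[i])
    f_iw <- bloch_simulate(wfd, cal, regions$water_freqs, s_iw)$flip
    f_ow <- bloch_simulate(wfd, cal, regions$water_freqs, s_ow)$flip
    f_f <- bloch_simulate(wfd, cal, regions$fat_freqs, s_f)$flip
    out$rmse_water[i] <-
      sqrt(mean(c((f_iw - alpha0)^2, (f_ow - 0)^2)))
    out$rmse_fat[i] <- sqrt(mean(f_f^2))
  }
  out
}
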