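#' Generate a synthetic pTx calibration set
#'
#' Emulates the calibration inputs of an 8-channel transmit head coil at
#' ultra-high field: spatially smooth complex transmit-sensitivity (B1+)
#' maps with azimuthal channel phase progression over an ellipsoidal
#' "brain" mask, plus a smooth off-resonance (dB0) field with localized
#' offsets. All randomness is controlled by `seed`.
#'
#' The coil model places `n_channels` loop-like elements on a ring around
#' the head. Each channel magnitude is a Gaussian falloff from its element
#' (center-bright in circularly-polarized combination), blended with a
#' spatially flat component; `b1_inhomogeneity = 0` gives spatially
#' constant channel magnitudes and phases, so the CP-mode combination
#' [cp_combine()] is perfectly homogeneous. Channel c carries the phase
#' increment 2*pi*(c-1)/n_channels. Maps are normalized so the CP
#' combination has unit magnitude at isocenter.
#'
#' @param n_channels number of transmit channels (>= 1).
#' @param grid a [grid_geometry()].
#' @param seed integer seed fixing all randomness.
#' @param b0_severity standard deviation (Hz) of the off-resonance field
#'   over the brain mask; 0 gives a uniformly zero field.
#' @param b1_inhomogeneity unitless scale between 0 and 1; 0 = perfectly
#'   homogeneous channels, 1 = full coil-like spatial structure.
#' @return an object of class `calibration_set` with elements `b1`
#'   (complex array, shape x channel), `db0` (Hz), `mask_brain`, `grid`,
#'   `n_channels`.
#' @export
generate_calibration <- function(n_channels = 8L, grid = grid_geometry(c(80, 80, 80), 3),
                                 seed = 1L, b0_severity = 50,
                                 b1_inhomogeneity = 1) {
  stopifnot(n_channels >= 1)
  if (any(grid$shape <= 0)) stop("invalid geometry")
  set.seed(as.integer(seed))
  sh <- grid$shape
  ax <- lapply(1:3, function(a) grid_axis_coords(grid, a))
  # voxel-center coordinate volumes (mm)
  X <- array(rep(ax[[1]], times = sh[2] * sh[3]), dim = sh)
  Y <- array(rep(rep(ax[[2]], each = sh[1]), times = sh[3]), dim = sh)
  Z <- array(rep(ax[[3]], each = sh[1] * sh[2]), dim = sh)

  extent <- sh * grid$voxel_size
  semi <- 0.42 * extent          # ellipsoid semi-axes, mm
  mask <- (X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2 <= 1
  if (!any(mask)) stop("invalid geometry: empty brain mask")

  w <- b1_inhomogeneity
  ring_r <- 1.15 * max(semi[1], semi[2])
  sigma <- 1.1 * max(semi)       # Gaussian falloff scale, mm
  theta_az <- atan2(Y, X)
  b1 <- array(0i, dim = c(sh, n_channels))
  for (c in seq_len(n_channels)) {
    phi_c <- 2 * pi * (c - 1) / n_channels
    dx <- X - ring_r * cos(phi_c)
    dy <- Y - ring_r * sin(phi_c)
    g <- exp(-(dx^2 + dy^2 + 0.15 * Z^2) / (2 * sigma^2))
    g <- g / max(g)
    # low-order random per-channel perturbation, smooth by construction
    pert <- rnorm(1, 0, 0.05) * (X / extent[1]) +
      rnorm(1, 0, 0.05) * (Y / extent[2]) +
      rnorm(1, 0, 0.05) * (Z / extent[3])
    mag <- (1 - w) + w * g * exp(pert)
    pha <- phi_c + w * (0.4 * sin(theta_az - phi_c) +
                          rnorm(1, 0, 0.1) * (Z / extent[3]))
    b1[, , , c] <- mag * exp(1i * pha)
  }
  # normalize: CP combination magnitude 1 at the voxel nearest isocenter
  i0 <- vapply(1:3, function(a) which.min(abs(ax[[a]])), integer(1))
  cp0 <- sum(vapply(seq_len(n_channels), function(c)
    b1[i0[1], i0[2], i0[3], c] * exp(-2i * pi * (c - 1) / n_channels),
    complex(1)))
  b1 <- b1 / Mod(cp0)

  db0 <- array(0, dim = sh)
  if (b0_severity > 0) {
    u <- X / extent[1]; v <- Y / extent[2]; s <- Z / extent[3]
    f <- rnorm(1) * u + rnorm(1) * v + rnorm(1) * s +
      rnorm(1) * (u^2 - v^2) + rnorm(1) * u * v + rnorm(1) * (s^2 - u^2)
    n_blob <- 3L
    idx_in <- which(mask)
    ctr <- idx_in[sample.int(length(idx_in), n_blob)]
    for (b in seq_len(n_blob)) {
      d2 <- (X - X[ctr[b]])^2 + (Y - Y[ctr[b]])^2 + (Z - Z[ctr[b]])^2
      f <- f + rnorm(1, 0, 1.5) * exp(-d2 / (2 * (0.12 * max(extent))^2))
    }
    f <- f - mean(f[mask])
    f_sd <- sd(f[mask])
    if (f_sd > 0) db0 <- f / f_sd * b0_severity
    db0 <- db0 - mean(db0[mask])
  }

  structure(list(b1 = b1, db0 = db0, mask_brain = mask, grid = grid,
                 n_channels = as.integer(n_channels)),
            class = "calibration_set")
}

#' Circularly-polarized (CP) mode combination of the channel maps
#'
#' Sums the channel sensitivities with the conjugate azimuthal phase
#' increments, mimicking birdcage-like single-channel operation.
#'
#' @param cal a [generate_calibration()] result.
#' @return complex 3D array.
#' @export
cp_combine <- function(cal) {
  out <- array(0i, dim = cal$grid$shape)
  for (c in seq_len(cal$n_channels))
    out <- out + cal$b1[, , , c] * exp(-2i * pi * (c - 1) / cal$n_channels)
  out
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("calibration_set: %d channels, grid %s, %d brain voxels\n",
              x$n_channels, paste(x$grid$shape, collapse = "x"),
              sum(x$mask_brain)))
  invisible(x)
}

#' Partition the brain into the four design regions
#'
#' Defines the spectral-spatial regions of the excitation target:
#' inside-slab water (passband), out-of-slab water, fat (the fat stopband
#' spans the whole brain), and the don't-care transition bands flanking
#' the passband. The transition band on each side of the passband has
#' width `transition_fraction * passband_width`, so the effective slab
#' thickness (FWHM of the ideal profile) is
#' `(1 + transition_fraction) * passband_width`.
#'
#' @param cal a `calibration_set`.
#' @param slab_center slab center along the slab axis, mm from isocenter.
#' @param passband_width width of the inside-slab water region, mm.
#' @param transition_fraction transition-band width as a fraction of the
#'   passband width (default 0.10).
#' @param water_freqs spectral sample(s) of the water passband, Hz.
#' @param fat_freqs spectral samples of the fat stopband, Hz.
#' @return an object of class `region_spec`.
#' @examples
#' cal <- generate_calibration(4, grid_geometry(c(16, 16, 16), 12), seed = 1)
#' rg <- define_regions(cal, 0, 48)
#' rg$effective_thickness  # 52.8 mm
#' @export
define_regions <- function(cal, slab_center = 0, passband_width = 48,
                           transition_fraction = 0.10,
                           water_freqs = 0,
                           fat_freqs = c(-1200, -1100, -1000, -900, -800)) {
  stopifnot(passband_width > 0, transition_fraction >= 0)
  grid <- cal$grid
  z <- grid_axis_coords(grid, grid$slab_axis)
  if (slab_center < min(z) || slab_center > max(z))
    stop("slab center outside grid extent")
  half <- passband_width / 2
  outer_half <- half + transition_fraction * passband_width
  if (outer_half > max(abs(z - slab_center)))
    warning("transition bands extend past the grid; clipped")
  dz <- abs(z - slab_center)
  in_line <- dz <= half
  dontcare_line <- dz > half & dz <= outer_half
  expand_line <- function(line) {
    perm <- order(c(grid$slab_axis, setdiff(1:3, grid$slab_axis)))
    n_other <- prod(grid$shape[-grid$slab_axis])
    aperm(array(rep(line, n_other),
                dim = c(grid$shape[grid$slab_axis],
                        grid$shape[setdiff(1:3, grid$slab_axis)])), perm)
  }
  inslab <- expand_line(in_line) & cal$mask_brain
  dontcare <- expand_line(dontcare_line) & cal$mask_brain
  outslab <- cal$mask_brain & !inslab & !dontcare
  structure(list(
    mask_inslab_water = inslab,
    mask_outslab_water = outslab,
    mask_fat = cal$mask_brain,
    mask_dontcare = dontcare,
    water_freqs = water_freqs, fat_freqs = fat_freqs,
    slab_center = slab_center, passband_width = passband_width,
    transition_fraction = transition_fraction,
    effective_thickness = (1 + transition_fraction) * passband_width),
    class = "region_spec")
}

#' Region-specific down-sampling of calibration data
#'
#' Down-samples calibration maps over a region to the requested in-plane
#' and through-plane resolutions by block averaging: the grid is
#' partitioned into cells of the requested size, and every cell that
#' intersects the region contributes one sample whose B1+/dB0 values are
#' the averages over the in-mask native voxels of the cell. Sample
#' positions are cell-center coordinates in mm relative to isocenter.
#'
#' @param cal a `calibration_set`.
#' @param region_mask logical volume on the calibration grid.
#' @param inplane_res target resolution (mm) in the two in-plane axes.
#' @param throughplane_res target resolution (mm) along the slab axis.
#' @return list with `pos` (n x 3 mm), `b1` (n x n_channels complex),
#'   `db0` (n), `n_native` (in-mask native voxels per cell).
#' @export
downsample_region <- function(cal, region_mask, inplane_res,
                              throughplane_res) {
  grid <- cal$grid
  res <- rep(inplane_res, 3)
  res[grid$slab_axis] <- throughplane_res
  if (any(res < grid$voxel_size - 1e-9))
    stop("target resolution below native voxel size")
  cs <- pmax(1L, as.integer(round(res / grid$voxel_size)))  # cell size, voxels
  idx <- which(region_mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    message("downsample_region: empty region mask")
    return(list(pos = matrix(numeric(0), 0, 3),
                b1 = matrix(complex(0), 0, cal$n_channels),
                db0 = numeric(0), n_native = integer(0)))
  }
  block <- sweep(idx - 1L, 2, cs, "%/%") + 1L      # block index per voxel
  nb <- (grid$shape - 1L) %/% cs + 1L
  id <- block[, 1] + nb[1] * (block[, 2] - 1L) + nb[1] * nb[2] * (block[, 3] - 1L)
  ord <- order(id)
  id <- id[ord]; idx <- idx[ord, , drop = FALSE]
  block <- block[ord, , drop = FALSE]
  grp <- match(id, unique(id))
  n_cells <- max(grp)
  lin <- idx[, 1] + grid$shape[1] * (idx[, 2] - 1L) +
    grid$shape[1] * grid$shape[2] * (idx[, 3] - 1L)

  n_native <- tabulate(grp, n_cells)
  avg <- function(v) as.vector(tapply(v, grp, mean))
  db0 <- avg(cal$db0[lin])
  nvox <- prod(grid$shape)
  b1 <- vapply(seq_len(cal$n_channels), function(c) {
    v <- cal$b1[lin + (c - 1) * nvox]
    complex(real = as.vector(tapply(Re(v), grp, mean)),
            imaginary = as.vector(tapply(Im(v), grp, mean)))
  }, complex(n_cells))
  b1 <- matrix(b1, nrow = n_cells)

  first <- !duplicated(grp)
  bidx <- block[first, , drop = FALSE]
  pos <- vapply(1:3, function(a) {
    lo <- (bidx[, a] - 1L) * cs[a] + 1L
    hi <- pmin(bidx[, a] * cs[a], grid$shape[a])
    grid$origin[a] + ((lo + hi) / 2 - 1) * grid$voxel_size[a]
  }, numeric(sum(first)))
  pos <- matrix(pos, ncol = 3)
  list(pos = pos, b1 = b1, db0 = db0, n_native = n_native)
}

#' Gather design samples for one region of a calibration set
#'
#' Convenience wrapper around [downsample_region()] returning the sample
#' structure consumed by [sta_matrix()].
#' @keywords internal
region_samples <- function(cal, mask, inplane_res, throughplane_res) {
  downsample_region(cal, mask, inplane_res, throughplane_res)
}
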