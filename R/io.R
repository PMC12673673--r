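#' Write a calibration set to a directory of NIfTI volumes
#'
#' Writes `b1_mag.nii.gz` and `b1_phase.nii.gz` (4D, channel as the 4th
#' dimension), `db0.nii.gz` (Hz), `brain.nii.gz` (0/1 mask) and a
#' plain-text `grid.txt` sidecar with the grid geometry. If `regions` is
#' supplied, a `labels.nii.gz` volume is also written with integer labels
#' 0 = don't-care/background, 1 = inside-slab water, 2 = out-of-slab
#' water, 3 = fat-only (brain voxels in no water region).
#'
#' @param cal a `calibration_set`.
#' @param dir output directory (created if needed).
#' @param regions optional `region_spec`.
#' @return `dir`, invisibly.
#' @export
write_calibration <- function(cal, dir, regions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vox <- cal$grid$voxel_size
  wr <- function(arr, name) {
    img <- RNifti::asNifti(arr, pixdim = c(vox, 1)[seq_along(dim(arr))])
    RNifti::writeNifti(img, file.path(dir, name))
  }
  wr(Mod(cal$b1), "b1_mag.nii.gz")
  wr(Arg(cal$b1), "b1_phase.nii.gz")
  wr(cal$db0, "db0.nii.gz")
  wr(array(as.integer(cal$mask_brain), dim = cal$grid$shape),
     "brain.nii.gz")
  if (!is.null(regions)) {
    lab <- array(0L, dim = cal$grid$shape)
    lab[regions$mask_fat] <- 3L
    lab[regions$mask_outslab_water] <- 2L
    lab[regions$mask_inslab_water] <- 1L
    lab[regions$mask_dontcare] <- 0L
    wr(lab, "labels.nii.gz")
  }
  meta <- c(
    sprintf("shape: %s", paste(cal$grid$shape, collapse = " ")),
    sprintf("voxel_size: %s", paste(cal$grid$voxel_size, collapse = " ")),
    sprintf("origin: %s", paste(cal$grid$origin, collapse = " ")),
    sprintf("slab_axis: %d", cal$grid$slab_axis),
    sprintf("n_channels: %d", cal$n_channels))
  writeLines(meta, file.path(dir, "grid.txt"))
  invisible(dir)
}

#' Read a calibration set written by [write_calibration()]
#'
#' @param dir directory containing the NIfTI volumes and `grid.txt`.
#' @return a `calibration_set`.
#' @export
read_calibration <- function(dir) {
  meta <- readLines(file.path(dir, "grid.txt"))
  get <- function(key) {
    line <- grep(paste0("^", key, ":"), meta, value = TRUE)
    as.numeric(strsplit(sub("^[a-z_]+: *", "", line), " ")[[1]])
  }
  grid <- grid_geometry(get("shape"), get("voxel_size"), get("origin"),
                        as.integer(get("slab_axis")))
  mag <- as.array(RNifti::readNifti(file.path(dir, "b1_mag.nii.gz")))
  pha <- as.array(RNifti::readNifti(file.path(dir, "b1_phase.nii.gz")))
  b1 <- mag * exp(1i * pha)
  db0 <- as.array(RNifti::readNifti(file.path(dir, "db0.nii.gz")))
  mask <- as.array(RNifti::readNifti(file.path(dir, "brain.nii.gz"))) > 0
  structure(list(b1 = array(b1, dim = dim(mag)), db0 = array(db0, grid$shape),
                 mask_brain = array(mask, grid$shape), grid = grid,
                 n_channels = as.integer(get("n_channels"))),
            class = "calibration_set")
}

#' Uniform spherical phantom calibration
#'
#' A doped-water sphere with homogeneous single-channel (CP-like)
#' transmit sensitivity and zero off-resonance, used for spatial-spectral
#' response simulations.
#'
#' @param grid a [grid_geometry()].
#' @param diameter_mm sphere diameter, mm (default 160).
#' @param n_channels number of channels (uniform unit CP combination).
#' @return a `calibration_set`.
#' @export
phantom_calibration <- function(grid = grid_geometry(c(60, 60, 60), 3),
                                diameter_mm = 160, n_channels = 1L) {
  co <- grid_coords(grid)
  r2 <- rowSums(co^2)
  mask <- array(r2 <= (diameter_mm / 2)^2, dim = grid$shape)
  if (!any(mask)) stop("invalid geometry: empty phantom mask")
  b1 <- array(0i, dim = c(grid$shape, n_channels))
  for (c in seq_len(n_channels))
    b1[, , , c] <- exp(2i * pi * (c - 1) / n_channels) / n_channels
  structure(list(b1 = b1, db0 = array(0, grid$shape), mask_brain = mask,
                 grid = grid, n_channels = as.integer(n_channels)),
            class = "calibration_set")
}
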