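#' Define the 3D voxel grid of a calibration volume
#'
#' The grid places voxel centers in millimetres relative to gradient
#' isocenter. By default the grid is centered on isocenter, i.e. the origin
#' is chosen so that the mean voxel-center coordinate along each axis is 0.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param voxel_size numeric, voxel size in mm; scalar (isotropic) or
#'   length 3.
#' @param origin mm coordinate of the center of voxel (1,1,1) relative to
#'   isocenter; defaults to centering the grid on isocenter.
#' @param slab_axis axis index (1, 2 or 3) along which the slab is selected.
#' @return an object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry(c(80, 80, 80), 3)
#' range(grid_axis_coords(g, 3))
#' @export
grid_geometry <- function(shape, voxel_size = 3, origin = NULL,
                          slab_axis = 3L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape <= 0L))
    stop("invalid geometry: 'shape' must be 3 positive integers")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("invalid geometry: 'voxel_size' must be positive")
  if (!(slab_axis %in% 1:3)) stop("'slab_axis' must be 1, 2 or 3")
  if (is.null(origin)) origin <- -(shape - 1) * voxel_size / 2
  structure(
    list(shape = shape, voxel_size = voxel_size,
         origin = as.numeric(origin), slab_axis = as.integer(slab_axis)),
    class = "grid_geometry")
}

#' Voxel-center coordinates along one grid axis
#'
#' @param grid a [grid_geometry()].
#' @param axis axis index.
#' @return numeric vector of mm coordinates relative to isocenter.
#' @export
grid_axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$voxel_size[axis]
}

#' Voxel-center coordinates of all (or selected) voxels
#'
#' @param grid a [grid_geometry()].
#' @param index optional matrix of 1-based voxel indices (n x 3) or a
#'   logical volume selecting voxels.
#' @return n x 3 matrix of mm coordinates relative to isocenter.
#' @export
grid_coords <- function(grid, index = NULL) {
  if (is.null(index)) {
    index <- as.matrix(expand.grid(seq_len(grid$shape[1]),
                                   seq_len(grid$shape[2]),
                                   seq_len(grid$shape[3])))
  } else if (is.logical(index) || (is.array(index) && !is.matrix(index))) {
    index <- which(array(as.logical(index), dim = grid$shape),
                   arr.ind = TRUE)
  }
  sweep(sweep(index - 1, 2, grid$voxel_size, "*"), 2, grid$origin, "+")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %s voxels at %s mm, slab axis %d\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              x$slab_axis))
  invisible(x)
}
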