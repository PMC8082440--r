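#' Voxel grid geometry
#'
#' A regular isotropic voxel grid centered on the isocenter. Axes follow the
#' patient coordinate convention used throughout the package: `x` points to
#' the patient's left, `y` anterior, `z` superior (cranial). Voxel centers are
#' symmetric about the origin.
#'
#' @param shape integer vector of length 3, voxel counts per axis (x, y, z).
#' @param voxel_mm isotropic voxel edge length in mm.
#' @return an object of class `rt_grid`.
#' @examples
#' g <- rt_grid(c(80, 55, 70), 4)
#' prod(g$shape) # number of voxels
#' @export
rt_grid <- function(shape = c(80L, 55L, 70L), voxel_mm = 4) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), voxel_mm > 0)
  structure(list(shape = shape, voxel_mm = as.numeric(voxel_mm)),
            class = "rt_grid")
}

#' @exportS3Method base::print
print.rt_grid <- function(x, ...) {
  cat(sprintf("<rt_grid %dx%dx%d voxels, %.3g mm isotropic (%.0fx%.0fx%.0f mm field)>\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_mm,
              x$shape[1] * x$voxel_mm, x$shape[2] * x$voxel_mm,
              x$shape[3] * x$voxel_mm))
  invisible(x)
}

#' Voxel center coordinates along each axis (mm, isocenter at origin)
#' @param grid an `rt_grid`.
#' @return list with numeric vectors `x`, `y`, `z`.
#' @keywords internal
grid_axes <- function(grid) {
  ax <- function(n, v) (seq_len(n) - (n + 1) / 2) * v
  list(x = ax(grid$shape[1], grid$voxel_mm),
       y = ax(grid$shape[2], grid$voxel_mm),
       z = ax(grid$shape[3], grid$voxel_mm))
}

#' Voxel volume in cc
#' @param grid an `rt_grid`.
#' @export
voxel_cc <- function(grid) grid$voxel_mm^3 / 1000

#' Structure volume in cc (voxel count times voxel volume)
#' @param mask logical array.
#' @param grid the `rt_grid` the mask lives on.
#' @export
mask_cc <- function(mask, grid) sum(mask) * voxel_cc(grid)

#' Cartesian coordinates (mm) of voxels given linear indices
#' @keywords internal
voxel_coords <- function(grid, idx) {
  n <- grid$shape
  i0 <- idx - 1L
  ix <- i0 %% n[1]
  iy <- (i0 %/% n[1]) %% n[2]
  iz <- i0 %/% (n[1] * n[2])
  cbind(x = (ix - (n[1] - 1) / 2) * grid$voxel_mm,
        y = (iy - (n[2] - 1) / 2) * grid$voxel_mm,
        z = (iz - (n[3] - 1) / 2) * grid$voxel_mm)
}
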