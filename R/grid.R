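#' Define a volumetric reconstruction grid
#'
#' A grid couples the array dimensions with physical voxel sizes (mm) and the
#' direction of the main magnetic field B0.  All volumes in the package
#' (susceptibility maps, tissue fields, k-space kernels and masks) live on a
#' grid.
#'
#' @param shape integer triple, array dimensions `(nx, ny, nz)`; each >= 8.
#' @param voxel_size positive real triple, voxel edge lengths in mm.
#' @param b0_direction unit 3-vector giving the B0 direction (default along
#'   the third axis).
#' @return An object of class `qsm_grid`.
#' @examples
#' g <- volume_grid(c(32, 32, 32))
#' @export
volume_grid <- function(shape, voxel_size = c(1, 1, 1),
                        b0_direction = c(0, 0, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(is.na(shape)))
    stop("'shape' must be an integer triple")
  if (any(shape < 8))
    stop("all grid dimensions must be at least 8")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be a positive real triple (mm)")
  b0_direction <- as.numeric(b0_direction)
  if (length(b0_direction) != 3 || any(!is.finite(b0_direction)))
    stop("'b0_direction' must be a real 3-vector")
  nrm <- sqrt(sum(b0_direction^2))
  if (abs(nrm - 1) > 1e-9)
    stop("'b0_direction' must be a unit vector (|b0| = 1 within 1e-9)")
  structure(
    list(shape = shape, voxel_size = voxel_size, b0_direction = b0_direction),
    class = "qsm_grid"
  )
}

#' @export
print.qsm_grid <- function(x, ...) {
  cat(sprintf(
    "<qsm_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, b0 = (%g, %g, %g)\n",
    x$shape[1], x$shape[2], x$shape[3],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$b0_direction[1], x$b0_direction[2], x$b0_direction[3]
  ))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size)) &&
    isTRUE(all.equal(a$b0_direction, b$b0_direction))
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(sprintf("%s must share the same grid (shape, voxel size, b0)", what))
  invisible(TRUE)
}

# discrete FFT frequencies (cycles/mm) in the transform's native ordering
fft_freq <- function(n, d = 1) {
  c(seq.int(0L, (n - 1L) %/% 2L), seq.int(-(n %/% 2L), -1L)) / (n * d)
}

# the three frequency coordinate arrays of a grid
kspace_coords <- function(grid) {
  n <- grid$shape
  fx <- fft_freq(n[1], grid$voxel_size[1])
  fy <- fft_freq(n[2], grid$voxel_size[2])
  fz <- fft_freq(n[3], grid$voxel_size[3])
  list(
    kx = array(fx, n),
    ky = array(rep(fy, each = n[1]), n),
    kz = array(rep(fz, each = n[1] * n[2]), n)
  )
}

check_scalar_field <- function(values, grid, name = "values") {
  if (!is.array(values) || length(dim(values)) != 3)
    stop(sprintf("'%s' must be a 3-D array", name))
  if (!all(dim(values) == grid$shape))
    stop(sprintf("'%s' does not match the grid shape", name))
  invisible(TRUE)
}
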