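#' Build the discrete dipole kernel
#'
#' The unit magnetic dipole has the k-space response
#' \deqn{D(k) = 1/3 - (k \cdot b_0)^2 / |k|^2,}
#' bounded between -2/3 (k parallel to B0) and 1/3 (k perpendicular to B0)
#' and zero on the magic-angle cone.  The ratio is evaluated on the grid's
#' discrete FFT frequencies in cycles/mm; only the ratio matters, so any
#' consistent frequency scaling gives the same kernel.
#'
#' The k = 0 bin is 0/0 in the formula and is set by `dc`; the default 0
#' demeans the simulated field, the standard convention when the absolute
#' field offset carries no information.
#'
#' @param grid a [volume_grid()].
#' @param dc value assigned at the k = 0 bin (default 0).
#' @return An object of class `qsm_kernel` with fields `values` (3-D array),
#'   `grid` and `dc`.
#' @examples
#' k <- dipole_kernel(volume_grid(c(16, 16, 16)))
#' range(k$values)  # -2/3 .. 1/3
#' @export
dipole_kernel <- function(grid, dc = 0) {
  if (!inherits(grid, "qsm_grid")) stop("'grid' must be a qsm_grid")
  if (any(grid$shape < 2))
    stop("degenerate grid: every dimension must have at least 2 frequencies")
  ks <- kspace_coords(grid)
  b0 <- grid$b0_direction
  kb2 <- (ks$kx * b0[1] + ks$ky * b0[2] + ks$kz * b0[3])^2
  k2 <- ks$kx^2 + ks$ky^2 + ks$kz^2
  ratio <- kb2 / k2
  # (1 - 3 r) / 3 attains 1/3 and -2/3 exactly at r = 0 and r = 1
  values <- (1 - 3 * ratio) / 3
  values[k2 == 0] <- dc
  structure(list(values = values, grid = grid, dc = dc),
            class = "qsm_kernel")
}

#' @export
print.qsm_kernel <- function(x, ...) {
  cat(sprintf(
    "<qsm_kernel> %d x %d x %d, D(k) in [%.4f, %.4f], D(0) = %g\n",
    x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
    min(x$values), max(x$values), x$dc
  ))
  invisible(x)
}
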