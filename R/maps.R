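#' Construct a susceptibility map
#'
#' A voxel grid of magnetic susceptibility values (ppm) together with a binary
#' tissue mask.  Values outside the mask are permitted (simulation sources may
#' extend beyond tissue), but every evaluation in the package is restricted to
#' the mask.
#'
#' @param values 3-D numeric array of susceptibility in ppm.
#' @param grid a [volume_grid()].
#' @param mask binary 3-D array of the same shape (default: all ones).
#' @return An object of class `qsm_chi`.
#' @export
susceptibility_map <- function(values, grid, mask = NULL) {
  check_scalar_field(values, grid)
  if (!all(is.finite(values)))
    stop("susceptibility values must be finite everywhere")
  mask <- check_mask(mask, grid)
  structure(list(values = values, grid = grid, mask = mask),
            class = "qsm_chi")
}

#' Construct a tissue-field map
#'
#' The local field perturbation (ppm of B0) on a grid, i.e. the input of the
#' dipole-inversion problem.
#'
#' @inheritParams susceptibility_map
#' @return An object of class `qsm_field`.
#' @export
tissue_field <- function(values, grid, mask = NULL) {
  check_scalar_field(values, grid)
  if (!all(is.finite(values)))
    stop("field values must be finite everywhere")
  mask <- check_mask(mask, grid)
  structure(list(values = values, grid = grid, mask = mask),
            class = "qsm_field")
}

check_mask <- function(mask, grid) {
  if (is.null(mask)) {
    mask <- array(1, grid$shape)
  } else {
    check_scalar_field(mask, grid, "mask")
    if (!all(mask %in% c(0, 1)))
      stop("'mask' must be binary (0/1)")
    mask <- array(as.numeric(mask), grid$shape)
  }
  mask
}

#' @export
print.qsm_chi <- function(x, ...) {
  v <- x$values[x$mask > 0]
  cat(sprintf(
    "<qsm_chi> %d x %d x %d, chi in [%.3g, %.3g] ppm over %d mask voxels\n",
    x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
    min(v), max(v), sum(x$mask)
  ))
  invisible(x)
}

#' @export
print.qsm_field <- function(x, ...) {
  v <- x$values[x$mask > 0]
  cat(sprintf(
    "<qsm_field> %d x %d x %d, field in [%.3g, %.3g] ppm over %d mask voxels\n",
    x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
    min(v), max(v), sum(x$mask)
  ))
  invisible(x)
}
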