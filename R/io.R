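#' Read a volume from a NIfTI file
#'
#' Reads a 3-D scalar NIfTI-1 volume and reconstructs the grid from its
#' voxel dimensions.  Non-3-D or non-scalar inputs are rejected.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param b0_direction B0 direction to attach to the grid (NIfTI files do
#'   not carry it).
#' @return A list with `values` (3-D array) and `grid` ([volume_grid()]).
#' @export
read_volume <- function(path, b0_direction = c(0, 0, 1)) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3)
    stop(sprintf(
      "expected a 3-D scalar volume, got %d dimensions (%s); 4-D inputs must be split first",
      length(d), paste(d, collapse = " x ")
    ))
  vox <- RNifti::pixdim(img)[1:3]
  values <- array(as.numeric(img), d)
  list(values = values, grid = volume_grid(d, vox, b0_direction))
}

#' Write a volume to a NIfTI file
#'
#' Stores a 3-D array (or the values of a map object) with the grid's voxel
#' sizes; data are written as 32-bit floats unless another datatype is
#' requested.
#'
#' @param x 3-D array, `qsm_chi` or `qsm_field`.
#' @param grid the [volume_grid()] (taken from `x` when it is a map object).
#' @param path output file (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype (default `"float"`).
#' @return The path, invisibly.
#' @export
write_volume <- function(x, grid = NULL, path, datatype = "float") {
  if (is.list(x) && !is.null(x$values)) {
    if (is.null(grid)) grid <- x$grid
    x <- x$values
  }
  if (is.null(grid)) stop("'grid' is required when 'x' is a plain array")
  check_scalar_field(x, grid)
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- grid$voxel_size
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a full simulation case to a directory
#'
#' Writes the susceptibility map, mask and tissue field of a simulated case
#' as NIfTI volumes plus a JSON sidecar describing the generating parameters,
#' so the case can be reproduced exactly.
#'
#' @param chi a [susceptibility_map()].
#' @param field a [tissue_field()] on the same grid.
#' @param dir output directory (created if needed).
#' @param params named list recorded in `params.json` (seeds, noise level,
#'   lesion settings, ...).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(chi, field, dir, params = list()) {
  stop_if_grid_mismatch(chi$grid, field$grid, "'chi' and 'field'")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(chi, path = file.path(dir, "chi.nii.gz"))
  write_volume(field, path = file.path(dir, "field.nii.gz"))
  write_volume(chi$mask, chi$grid, file.path(dir, "mask.nii.gz"),
               datatype = "uint8")
  params$grid <- list(shape = chi$grid$shape,
                      voxel_size = chi$grid$voxel_size,
                      b0_direction = chi$grid$b0_direction)
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
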