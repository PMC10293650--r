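#' Build complementary k-space fidelity masks
#'
#' Thresholding the dipole kernel magnitude partitions k-space into a
#' low-fidelity region (|D(k)| <= tau, where the susceptibility information
#' is weakly encoded and noise is amplified on inversion) and its
#' high-fidelity complement.  The boundary |D| = tau and the k = 0 bin
#' (D(0) = 0 by default) belong to the low mask.
#'
#' @param kernel a [dipole_kernel()].
#' @param tau threshold in (0, 2/3].
#' @return An object of class `qsm_fidelity_masks` with binary arrays
#'   `low` and `high` satisfying `low + high == 1` everywhere.
#' @examples
#' k <- dipole_kernel(volume_grid(c(16, 16, 16)))
#' m <- fidelity_masks(k, 0.3)
#' @export
fidelity_masks <- function(kernel, tau) {
  if (!inherits(kernel, "qsm_kernel")) stop("'kernel' must be a qsm_kernel")
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) ||
      tau <= 0 || tau > 2 / 3)
    stop("'tau' must lie in (0, 2/3]")
  low <- array(as.numeric(abs(kernel$values) <= tau), kernel$grid$shape)
  structure(
    list(low = low, high = 1 - low, tau = tau, grid = kernel$grid),
    class = "qsm_fidelity_masks"
  )
}

#' @export
print.qsm_fidelity_masks <- function(x, ...) {
  cat(sprintf(
    "<qsm_fidelity_masks> tau = %g, low-fidelity fraction %.3f\n",
    x$tau, mean(x$low)
  ))
  invisible(x)
}

#' Split a tissue field into low- and high-fidelity components
#'
#' Applies the complementary k-space masks to the field spectrum and returns
#' both components in image space.  The masks partition the spectrum, so the
#' two components sum back to the input (to round-off), and both are real
#' because the masks inherit the kernel's k -> -k symmetry.
#'
#' @param field a [tissue_field()].
#' @param masks a [fidelity_masks()] pair on the same grid.
#' @return A list with [tissue_field()] entries `low` and `high`.
#' @export
decompose_field <- function(field, masks) {
  if (!inherits(field, "qsm_field")) stop("'field' must be a qsm_field")
  if (!inherits(masks, "qsm_fidelity_masks"))
    stop("'masks' must be a qsm_fidelity_masks")
  stop_if_grid_mismatch(field$grid, masks$grid, "'field' and 'masks'")
  spec <- fft3(field$values)
  low <- Re(ifft3(masks$low * spec))
  high <- Re(ifft3(masks$high * spec))
  list(
    low = tissue_field(low, field$grid, field$mask),
    high = tissue_field(high, field$grid, field$mask)
  )
}

#' Assemble the multichannel network input
#'
#' Stacks (1) the original tissue field, (2) its high-fidelity component and
#' (3) its low-fidelity component as channels of a 4-D array, the input of
#' the multichannel inversion network.  `channels` selects a subset in this
#' fixed numbering for ablation experiments.
#'
#' @inheritParams decompose_field
#' @param channels integer subset of `c(1, 2, 3)`; the output keeps the
#'   requested channels in the stated order.
#' @return 4-D array `(nx, ny, nz, length(channels))` with a `channels`
#'   attribute recording the selection.
#' @export
assemble_channels <- function(field, masks, channels = 1:3) {
  channels <- as.integer(channels)
  if (length(channels) < 1 || anyDuplicated(channels) ||
      !all(channels %in% 1:3))
    stop("'channels' must be a non-empty subset of 1:3 without duplicates")
  parts <- decompose_field(field, masks)
  all3 <- list(field$values, parts$high$values, parts$low$values)
  out <- array(0, c(field$grid$shape, length(channels)))
  for (i in seq_along(channels)) out[, , , i] <- all3[[channels[i]]]
  attr(out, "channels") <- channels
  out
}

#' Export a fidelity mask pair as a label volume
#'
#' Encodes the pair as a single 8-bit volume (1 = low-fidelity, 0 = high)
#' for visual inspection in a NIfTI viewer.
#'
#' @param masks a [fidelity_masks()] pair.
#' @param path output file (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_fidelity_masks <- function(masks, path) {
  if (!inherits(masks, "qsm_fidelity_masks"))
    stop("'masks' must be a qsm_fidelity_masks")
  write_volume(masks$low, masks$grid, path, datatype = "uint8")
}
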