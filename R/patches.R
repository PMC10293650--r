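#' Extract overlapping training patches
#'
#' Slides a 3-D window over the volume on a regular lattice with stride
#' `round(patch_size * (1 - overlap))` per axis; the final origin on each
#' axis is clipped flush to the boundary so edge anatomy is kept.  Patches
#' whose tissue fraction (mask voxels / patch voxels) falls below
#' `tissue_fraction_min` are discarded.
#'
#' @param channels 4-D array `(nx, ny, nz, n_channels)`, e.g. from
#'   [assemble_channels()].
#' @param label a [susceptibility_map()] on the same grid (training target).
#' @param mask binary 3-D array (defaults to the label's mask).
#' @param patch_size patch edge length(s), one integer or a triple
#'   (default 64).
#' @param overlap_fraction fractional overlap between neighbouring patches in
#'   `[0, 1)` (default 0.66).
#' @param tissue_fraction_min minimum tissue fraction to keep a patch
#'   (default 0.10).
#' @return An object of class `qsm_patch_set`: a list with `items` (each a
#'   list of `channels`, `label`, `mask`, `origin`) and the extraction
#'   parameters.
#' @export
extract_patches <- function(channels, label, mask = NULL,
                            patch_size = 64, overlap_fraction = 0.66,
                            tissue_fraction_min = 0.10) {
  if (!is.array(channels) || length(dim(channels)) != 4)
    stop("'channels' must be a 4-D array (nx, ny, nz, n_channels)")
  if (!inherits(label, "qsm_chi")) stop("'label' must be a qsm_chi")
  vol <- dim(channels)[1:3]
  if (!all(vol == label$grid$shape))
    stop("'channels' and 'label' shapes differ")
  if (is.null(mask)) mask <- label$mask
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("'overlap_fraction' must lie in [0, 1)")
  patch_size <- as.integer(rep(patch_size, length.out = 3))
  if (any(patch_size > vol))
    stop("patch size exceeds the volume")
  stride <- pmax(1L, as.integer(round(patch_size * (1 - overlap_fraction))))
  origin_axis <- function(n, p, s) {
    o <- seq.int(1L, n - p + 1L, by = s)
    if (o[length(o)] != n - p + 1L) o <- c(o, n - p + 1L)
    o
  }
  ox <- origin_axis(vol[1], patch_size[1], stride[1])
  oy <- origin_axis(vol[2], patch_size[2], stride[2])
  oz <- origin_axis(vol[3], patch_size[3], stride[3])
  items <- list()
  for (z in oz) for (y in oy) for (x in ox) {
    ix <- x:(x + patch_size[1] - 1L)
    iy <- y:(y + patch_size[2] - 1L)
    iz <- z:(z + patch_size[3] - 1L)
    mpatch <- mask[ix, iy, iz]
    if (mean(mpatch) < tissue_fraction_min) next
    items[[length(items) + 1L]] <- list(
      channels = channels[ix, iy, iz, , drop = FALSE],
      label = label$values[ix, iy, iz],
      mask = mpatch,
      origin = c(x, y, z)
    )
  }
  structure(
    list(items = items, patch_size = patch_size, stride = stride,
         overlap_fraction = overlap_fraction,
         tissue_fraction_min = tissue_fraction_min,
         n_channels = dim(channels)[4]),
    class = "qsm_patch_set"
  )
}

#' @export
print.qsm_patch_set <- function(x, ...) {
  cat(sprintf(
    "<qsm_patch_set> %d patches of %s (stride %s, %d channels)\n",
    length(x$items), paste(x$patch_size, collapse = "x"),
    paste(x$stride, collapse = "x"), x$n_channels
  ))
  invisible(x)
}

#' @export
length.qsm_patch_set <- function(x) length(x$items)

#' Save / load a patch set
#'
#' Runtime persistence of extracted patch sets (origins and parameters
#' included) using R's native serialization.
#'
#' @param patches a `qsm_patch_set`.
#' @param path file path.
#' @return `save_patches()` the path invisibly; `load_patches()` the patch
#'   set.
#' @export
save_patches <- function(patches, path) {
  if (!inherits(patches, "qsm_patch_set"))
    stop("'patches' must be a qsm_patch_set")
  saveRDS(patches, path)
  invisible(path)
}

#' @rdname save_patches
#' @export
load_patches <- function(path) {
  p <- readRDS(path)
  if (!inherits(p, "qsm_patch_set")) stop("file does not hold a qsm_patch_set")
  p
}

# trilinear sample of a 3-D array at fractional voxel coordinates (1-based);
# coordinates outside the volume return `fill`
trilinear_sample <- function(arr, xs, ys, zs, fill = 0) {
  n <- dim(arr)
  x0 <- floor(xs); y0 <- floor(ys); z0 <- floor(zs)
  fx <- xs - x0; fy <- ys - y0; fz <- zs - z0
  out <- numeric(length(xs))
  gather <- function(ix, iy, iz) {
    ok <- ix >= 1 & ix <= n[1] & iy >= 1 & iy <= n[2] & iz >= 1 & iz <= n[3]
    v <- numeric(length(ix))
    if (any(ok))
      v[ok] <- arr[cbind(ix[ok], iy[ok], iz[ok])]
    v[!ok] <- fill
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    out <- out + w * gather(x0 + dx, y0 + dy, z0 + dz)
  }
  out
}

#' Rotation augmentation of a susceptibility map
#'
#' Rotates the susceptibility map about an axis perpendicular to B0 (the
#' second grid axis for the default B0 along z) using trilinear
#' interpolation, re-binarizes the mask at 0.5, and re-simulates the paired
#' tissue field from the rotated map through the forward model -- exact for
#' synthetic data, where the field is defined by the susceptibility rather
#' than measured.
#'
#' @param chi a [susceptibility_map()].
#' @param angle_deg rotation angle in degrees; |angle| <= `max_angle`.
#' @param noise_sd,seed noise parameters passed to [forward_field()].
#' @param max_angle largest admissible |angle| (default 15, the conventional
#'   augmentation range relative to B0).
#' @return A list with the rotated `chi` and the re-simulated `field`.
#' @export
augment_rotation <- function(chi, angle_deg, noise_sd = 0, seed = NULL,
                             max_angle = 15) {
  if (!inherits(chi, "qsm_chi")) stop("'chi' must be a qsm_chi")
  if (abs(angle_deg) > max_angle)
    stop(sprintf("|angle| must not exceed %g degrees", max_angle))
  n <- chi$grid$shape
  ctr <- (n + 1) / 2
  th <- angle_deg * pi / 180
  # inverse rotation (gather): rotate sample coordinates by -theta about y
  cx <- array(seq_len(n[1]) - ctr[1], n)
  cz <- array(rep(seq_len(n[3]) - ctr[3], each = n[1] * n[2]), n)
  xs <- as.vector(cos(th) * cx + sin(th) * cz + ctr[1])
  ys <- as.vector(array(rep(seq_len(n[2]), each = n[1]), n))
  zs <- as.vector(-sin(th) * cx + cos(th) * cz + ctr[3])
  vals <- array(trilinear_sample(chi$values, xs, ys, zs), n)
  m <- array(as.numeric(trilinear_sample(chi$mask, xs, ys, zs) >= 0.5), n)
  chi_rot <- susceptibility_map(vals, chi$grid, m)
  field <- forward_field(chi_rot, noise_sd = noise_sd, seed = seed)
  list(chi = chi_rot, field = field)
}

#' Split phantoms into train / validation / test groups
#'
#' Mirrors a subject-level split at the phantom level: indices `1:n` are
#' shuffled (seeded) and partitioned by the given ratio (default 5/2/5).
#'
#' @param n number of phantoms.
#' @param ratio positive weights for train, validation, test.
#' @param seed integer seed.
#' @return A list of integer index vectors `train`, `val`, `test`.
#' @export
split_phantoms <- function(n, ratio = c(5, 2, 5), seed = 1L) {
  if (length(ratio) != 3 || any(ratio < 0) || sum(ratio) == 0)
    stop("'ratio' must be three non-negative weights")
  idx <- with_seed(seed, sample.int(n))
  counts <- floor(n * ratio / sum(ratio))
  while (sum(counts) < n) {
    counts[which.max(n * ratio / sum(ratio) - counts)] <-
      counts[which.max(n * ratio / sum(ratio) - counts)] + 1L
  }
  list(
    train = sort(idx[seq_len(counts[1])]),
    val = sort(idx[counts[1] + seq_len(counts[2])]),
    test = sort(idx[counts[1] + counts[2] + seq_len(counts[3])])
  )
}
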