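#' Specify a synthetic susceptibility phantom
#'
#' The phantom emulates a labelled brain dataset: an ellipsoidal "brain"
#' mask containing randomly placed piecewise-constant susceptibility sources
#' (spheres, ellipsoids, cuboids) on a constant background.  Tissue-range
#' defaults (chi in (-0.2, 0.2) ppm) follow literature-typical brain values;
#' they are configurable, not measured constants.
#'
#' @param grid a [volume_grid()].
#' @param n_sources number of random sources (>= 0).
#' @param source_shapes subset of `c("sphere", "ellipsoid", "cuboid")`.
#' @param chi_range susceptibility interval (ppm) the source values are drawn
#'   from, uniformly.
#' @param background_chi constant background susceptibility inside the mask
#'   (ppm).
#' @param brain_mask_axes ellipsoid semi-axes as fractions of the grid
#'   half-extent, in (0, 1].
#' @param source_radius_range source half-size range in voxels.
#' @param seed integer seed; the phantom is a deterministic function of the
#'   spec.
#' @return An object of class `qsm_phantom_spec`.
#' @export
phantom_spec <- function(grid,
                         n_sources = 40,
                         source_shapes = c("sphere", "ellipsoid", "cuboid"),
                         chi_range = c(-0.2, 0.2),
                         background_chi = 0,
                         brain_mask_axes = c(0.8, 0.9, 0.75),
                         source_radius_range = NULL,
                         seed = 1L) {
  if (!inherits(grid, "qsm_grid")) stop("'grid' must be a qsm_grid")
  if (n_sources < 0) stop("'n_sources' must be non-negative")
  source_shapes <- match.arg(source_shapes,
                             c("sphere", "ellipsoid", "cuboid"),
                             several.ok = TRUE)
  if (length(chi_range) != 2 || any(!is.finite(chi_range)) ||
      chi_range[1] > chi_range[2])
    stop("'chi_range' must be a finite interval")
  if (length(brain_mask_axes) != 3 || any(brain_mask_axes <= 0) ||
      any(brain_mask_axes > 1))
    stop("'brain_mask_axes' must lie in (0, 1]^3")
  if (is.null(source_radius_range))
    source_radius_range <- c(2, max(3, round(min(grid$shape) / 8)))
  structure(
    list(grid = grid, n_sources = as.integer(n_sources),
         source_shapes = source_shapes, chi_range = chi_range,
         background_chi = background_chi, brain_mask_axes = brain_mask_axes,
         source_radius_range = source_radius_range, seed = as.integer(seed)),
    class = "qsm_phantom_spec"
  )
}

# ellipsoidal brain mask of a spec
ellipsoid_mask <- function(grid, axes_frac) {
  n <- grid$shape
  ctr <- (n + 1) / 2
  semi <- axes_frac * (n / 2)
  dx <- array((seq_len(n[1]) - ctr[1]) / semi[1], n)
  dy <- array(rep((seq_len(n[2]) - ctr[2]) / semi[2], each = n[1]), n)
  dz <- array(rep((seq_len(n[3]) - ctr[3]) / semi[3], each = n[1] * n[2]), n)
  array(as.numeric(dx^2 + dy^2 + dz^2 <= 1), n)
}

# indicator of one source at `center` with half-sizes `semi` (voxels)
source_indicator <- function(grid, shape, center, semi) {
  n <- grid$shape
  dx <- array((seq_len(n[1]) - center[1]) / semi[1], n)
  dy <- array(rep((seq_len(n[2]) - center[2]) / semi[2], each = n[1]), n)
  dz <- array(rep((seq_len(n[3]) - center[3]) / semi[3],
                  each = n[1] * n[2]), n)
  if (shape == "cuboid") {
    (abs(dx) <= 1) & (abs(dy) <= 1) & (abs(dz) <= 1)
  } else {
    dx^2 + dy^2 + dz^2 <= 1
  }
}

#' Generate a synthetic susceptibility phantom
#'
#' Draws `n_sources` sources with uniform susceptibility in `chi_range`,
#' placed uniformly inside the ellipsoidal brain mask, added to the constant
#' background.  Source values accumulate where sources overlap.  The result
#' is a deterministic function of the spec (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @return A [susceptibility_map()] with the ellipsoidal mask.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "qsm_phantom_spec"))
    stop("'spec' must be a qsm_phantom_spec")
  grid <- spec$grid
  mask <- ellipsoid_mask(grid, spec$brain_mask_axes)
  rmax <- max(spec$source_radius_range)
  if (spec$n_sources > 0 && any(grid$shape < 4 * rmax))
    stop("grid too small for the requested source sizes")
  chi <- array(0, grid$shape)
  with_seed(spec$seed, {
    inside <- which(mask > 0)
    if (spec$n_sources > 0 && length(inside) == 0)
      stop("empty brain mask")
    for (i in seq_len(spec$n_sources)) {
      idx <- inside[sample.int(length(inside), 1)]
      center <- arrayInd(idx, grid$shape)[1, ]
      shape <- spec$source_shapes[sample.int(length(spec$source_shapes), 1)]
      semi <- runif(3, spec$source_radius_range[1], spec$source_radius_range[2])
      if (shape == "sphere") semi <- rep(semi[1], 3)
      val <- runif(1, spec$chi_range[1], spec$chi_range[2])
      ind <- source_indicator(grid, shape, center, semi)
      chi <- chi + val * ind
    }
  })
  chi <- (chi + spec$background_chi) * mask
  susceptibility_map(chi, grid, mask)
}

#' Insert a high-susceptibility lesion
#'
#' Overwrites the susceptibility inside a sphere with `chi_lesion` (ppm),
#' emulating an intracerebral-hemorrhage-like source.  The lesion must lie
#' fully inside the tissue mask.
#'
#' @param chi a [susceptibility_map()].
#' @param center lesion center in voxel coordinates.
#' @param radius lesion radius in voxels (> 0).
#' @param chi_lesion lesion susceptibility in ppm (default 1.0, a
#'   literature-typical hemorrhage-like value).
#' @return The modified [susceptibility_map()].
#' @export
insert_lesion <- function(chi, center, radius, chi_lesion = 1.0) {
  if (!inherits(chi, "qsm_chi")) stop("'chi' must be a qsm_chi")
  if (radius <= 0) stop("'radius' must be positive")
  n <- chi$grid$shape
  dx <- array(seq_len(n[1]) - center[1], n)
  dy <- array(rep(seq_len(n[2]) - center[2], each = n[1]), n)
  dz <- array(rep(seq_len(n[3]) - center[3], each = n[1] * n[2]), n)
  inside <- dx^2 + dy^2 + dz^2 <= radius^2
  if (!any(inside)) stop("lesion contains no voxels")
  if (any(chi$mask[inside] == 0))
    stop("lesion extends outside the tissue mask")
  values <- chi$values
  values[inside] <- chi_lesion
  susceptibility_map(values, chi$grid, chi$mask)
}

#' Simulate a hemorrhage case
#'
#' Inserts the lesion into a base susceptibility map, then simulates its
#' tissue field by dipole convolution plus Gaussian noise.  Returns both the
#' lesioned ground truth and the noisy field.
#'
#' @param chi_base a [susceptibility_map()].
#' @param center,radius,chi_lesion lesion parameters, see [insert_lesion()].
#' @param noise_sd Gaussian noise level in ppm (default 0.005, small relative
#'   to tissue contrast).
#' @param seed integer noise seed.
#' @return A list with elements `chi` (lesioned map) and `field`
#'   ([tissue_field()]).
#' @export
simulate_hemorrhage_case <- function(chi_base, center, radius,
                                     chi_lesion = 1.0, noise_sd = 0.005,
                                     seed = NULL) {
  chi <- insert_lesion(chi_base, center, radius, chi_lesion)
  field <- forward_field(chi, noise_sd = noise_sd, seed = seed)
  list(chi = chi, field = field)
}
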