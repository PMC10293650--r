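# FFT helpers: forward transform and unitary-inverse pair
fft3 <- function(x) stats::fft(x)
ifft3 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# apply a real k-space filter to a real volume, returning the real part after
# checking that the imaginary residue is negligible
apply_kfilter <- function(values, kvalues) {
  out <- ifft3(kvalues * fft3(values))
  re <- Re(out)
  nrm <- sqrt(sum(re^2))
  if (nrm > 0 && sqrt(sum(Im(out)^2)) > 1e-8 * nrm)
    warning("imaginary residue above 1e-8 of the signal norm; ",
            "the k-space filter may not be Hermitian-symmetric")
  re
}

# run code with a local RNG state seeded by `seed` (NULL = use current RNG)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  } else {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate the tissue field of a susceptibility distribution
#'
#' Applies the magnetostatic forward model \eqn{B(k) = D(k) X(k) + N(k)}:
#' the susceptibility map is filtered by the dipole kernel in k-space and
#' (optionally) corrupted with i.i.d. Gaussian noise added in image space.
#'
#' @param chi a [susceptibility_map()].
#' @param kernel a [dipole_kernel()] on the same grid; built on the fly when
#'   `NULL`.
#' @param noise_sd standard deviation (ppm) of the additive Gaussian noise;
#'   0 for a noise-free field.
#' @param seed integer seed for the noise (`NULL` = current RNG state).
#' @param pad zero-padding (voxels appended per axis) applied around the
#'   volume before the transform.  The default 0 keeps the plain circular
#'   spectral product `B(k) = D(k) X(k)` on the grid -- the algebraic model
#'   that truncated inversion and the training loss assume.  For physical
#'   simulation of compact sources, padding (e.g. by the grid size, doubling
#'   each dimension) suppresses the wrap-around contribution of periodic
#'   source replicas; a `kernel` cannot be supplied in that case because the
#'   filter lives on the padded grid.
#' @return A [tissue_field()] carrying the mask of `chi`.
#' @examples
#' g <- volume_grid(c(16, 16, 16))
#' chi <- susceptibility_map(array(0, g$shape), g)
#' f <- forward_field(chi)            # zero field
#' @export
forward_field <- function(chi, kernel = NULL, noise_sd = 0, seed = NULL,
                          pad = 0) {
  if (!inherits(chi, "qsm_chi")) stop("'chi' must be a qsm_chi")
  pad <- as.integer(rep(pad, length.out = 3))
  if (any(pad < 0)) stop("'pad' must be non-negative")
  if (any(pad > 0)) {
    if (!is.null(kernel))
      stop("'kernel' cannot be combined with 'pad'; the padded-grid kernel ",
           "is built internally")
    n <- chi$grid$shape
    pgrid <- volume_grid(n + pad, chi$grid$voxel_size, chi$grid$b0_direction)
    xp <- array(0, pgrid$shape)
    xp[seq_len(n[1]), seq_len(n[2]), seq_len(n[3])] <- chi$values
    vp <- apply_kfilter(xp, dipole_kernel(pgrid)$values)
    values <- vp[seq_len(n[1]), seq_len(n[2]), seq_len(n[3])]
  } else {
    if (is.null(kernel)) kernel <- dipole_kernel(chi$grid)
    if (!inherits(kernel, "qsm_kernel")) stop("'kernel' must be a qsm_kernel")
    stop_if_grid_mismatch(chi$grid, kernel$grid, "'chi' and 'kernel'")
    values <- apply_kfilter(chi$values, kernel$values)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0)
    stop("'noise_sd' must be a single non-negative number")
  if (noise_sd > 0)
    values <- values + with_seed(seed, array(
      rnorm(length(values), sd = noise_sd), dim(values)
    ))
  tissue_field(values, chi$grid, chi$mask)
}

#' Analytic field of a uniform sphere
#'
#' Closed-form magnetostatics oracle for the forward model: a sphere of
#' susceptibility contrast `delta_chi` produces zero internal field shift and
#' an external dipolar pattern
#' \deqn{\Delta B / B_0 = (\Delta\chi / 3) (R / r)^3 (3\cos^2\theta - 1),}
#' with \eqn{\theta} the angle between the offset from the center and B0.
#' Used to validate the FFT implementation independent of any transform
#' conventions.
#'
#' @param grid a [volume_grid()] with isotropic voxels.
#' @param center sphere center in voxel coordinates (1-based, may be
#'   fractional).
#' @param radius sphere radius in voxels (>= 2); the sphere must lie strictly
#'   inside the grid.
#' @param delta_chi susceptibility contrast in ppm.
#' @return A [tissue_field()] (full mask).
#' @export
analytic_sphere_field <- function(grid, center, radius, delta_chi) {
  if (!inherits(grid, "qsm_grid")) stop("'grid' must be a qsm_grid")
  if (max(grid$voxel_size) - min(grid$voxel_size) > 1e-12)
    stop("the sphere oracle requires isotropic voxels")
  if (radius < 2) stop("'radius' must be at least 2 voxels")
  if (any(center - radius < 1) || any(center + radius > grid$shape))
    stop("sphere touches or crosses the grid boundary")
  n <- grid$shape
  dx <- array(seq_len(n[1]) - center[1], n)
  dy <- array(rep(seq_len(n[2]) - center[2], each = n[1]), n)
  dz <- array(rep(seq_len(n[3]) - center[3], each = n[1] * n[2]), n)
  b0 <- grid$b0_direction
  r2 <- dx^2 + dy^2 + dz^2
  proj <- dx * b0[1] + dy * b0[2] + dz * b0[3]
  cos2 <- ifelse(r2 > 0, proj^2 / r2, 0)
  vals <- ifelse(
    r2 > radius^2,
    (delta_chi / 3) * (radius^2 / r2)^1.5 * (3 * cos2 - 1),
    0
  )
  tissue_field(array(vals, n), grid)
}

#' Spherical susceptibility phantom
#'
#' Piecewise-constant sphere of susceptibility `delta_chi` (ppm) on an
#' otherwise zero background; the companion of [analytic_sphere_field()].
#'
#' @inheritParams analytic_sphere_field
#' @param mask optional binary mask for the returned map (default all ones).
#' @return A [susceptibility_map()].
#' @export
sphere_phantom <- function(grid, center, radius, delta_chi, mask = NULL) {
  if (!inherits(grid, "qsm_grid")) stop("'grid' must be a qsm_grid")
  n <- grid$shape
  dx <- array(seq_len(n[1]) - center[1], n)
  dy <- array(rep(seq_len(n[2]) - center[2], each = n[1]), n)
  dz <- array(rep(seq_len(n[3]) - center[3], each = n[1] * n[2]), n)
  inside <- (dx^2 + dy^2 + dz^2) <= radius^2
  susceptibility_map(array(delta_chi * inside, n), grid, mask)
}
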