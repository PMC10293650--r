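# shared fixtures and independent brute-force oracles

grid16 <- function() volume_grid(c(16, 16, 16))

rand_volume <- function(n = 16, seed = 1, sd = 1) {
  set.seed(seed)
  array(rnorm(n^3, sd = sd), c(n, n, n))
}

# radial distance array from a center, in voxels
radius_from <- function(shape, center) {
  dx <- array(seq_len(shape[1]) - center[1], shape)
  dy <- array(rep(seq_len(shape[2]) - center[2], each = shape[1]), shape)
  dz <- array(rep(seq_len(shape[3]) - center[3],
                  each = shape[1] * shape[2]), shape)
  sqrt(dx^2 + dy^2 + dz^2)
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

# naive direct 3^3 (or 1^3) convolution, zero padding, used as the oracle for
# the compiled layers; x (nx,ny,nz,ci,n), w (k,k,k,ci,co)
naive_conv3 <- function(x, w, b, stride = 1) {
  d <- dim(x); k <- dim(w)[1]; ci <- dim(w)[4]; co <- dim(w)[5]
  pad <- (k - 1) %/% 2
  os <- (d[1:3] + 2 * pad - k) %/% stride + 1
  y <- array(0, c(os, co, d[5]))
  for (s in seq_len(d[5])) for (oc in seq_len(co))
    for (z in seq_len(os[3])) for (yy in seq_len(os[2]))
      for (xx in seq_len(os[1])) {
        acc <- b[oc]
        for (icc in seq_len(ci)) for (tz in 1:k) for (ty in 1:k)
          for (tx in 1:k) {
            ix <- (xx - 1) * stride + tx - pad
            iy <- (yy - 1) * stride + ty - pad
            iz <- (z - 1) * stride + tz - pad
            if (ix >= 1 && ix <= d[1] && iy >= 1 && iy <= d[2] &&
                iz >= 1 && iz <= d[3])
              acc <- acc + x[ix, iy, iz, icc, s] * w[tx, ty, tz, icc, oc]
          }
        y[xx, yy, z, oc, s] <- acc
      }
  y
}

# central-difference numeric gradient of f at a
numeric_grad <- function(f, a, h = 1e-3) {
  g <- a * 0
  for (i in seq_along(a)) {
    ap <- a; ap[i] <- ap[i] + h
    am <- a; am[i] <- am[i] - h
    g[i] <- (f(ap) - f(am)) / (2 * h)
  }
  g
}

# a small phantom + field + channels + patches, shared by training tests
tiny_training_setup <- function(seed = 7, grid_n = 32, patch = 16,
                                overlap = 0.5, tau = 0.3, n_sources = 10) {
  grid <- volume_grid(rep(grid_n, 3))
  chi <- generate_phantom(phantom_spec(grid, n_sources = n_sources,
                                       seed = seed))
  field <- forward_field(chi, noise_sd = 0.005, seed = seed)
  masks <- fidelity_masks(dipole_kernel(grid), tau)
  channels <- assemble_channels(field, masks)
  patches <- extract_patches(channels, chi, patch_size = patch,
                             overlap_fraction = overlap)
  list(grid = grid, chi = chi, field = field, masks = masks,
       channels = channels, patches = patches)
}
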