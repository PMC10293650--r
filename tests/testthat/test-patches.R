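test_that("patch origins follow the clipped stride lattice", {
  g <- volume_grid(c(64, 64, 64))
  chi <- susceptibility_map(array(0, g$shape), g)
  ch <- array(0, c(g$shape, 1))
  # single flush placement when the patch fills the volume
  ps <- extract_patches(ch, chi, patch_size = 64, overlap_fraction = 0)
  expect_equal(length(ps), 1L)
  expect_equal(ps$items[[1]]$origin, c(1, 1, 1))
  # 64^3 patches on a 128^3 volume at 66 % overlap: stride 22,
  # origins 1, 23, 45, 65 (flush) per axis -> 4^3 patches
  g2 <- volume_grid(c(128, 64, 64))
  chi2 <- susceptibility_map(array(0, g2$shape), g2)
  ch2 <- array(0, c(g2$shape, 1))
  ps2 <- extract_patches(ch2, chi2, patch_size = c(64, 64, 64),
                         overlap_fraction = 0.66)
  expect_equal(ps2$stride, c(22L, 22L, 22L))
  ox <- sort(unique(vapply(ps2$items, function(it) it$origin[1], 0)))
  expect_equal(ox, c(1, 23, 45, 65))
  expect_equal(length(ps2), 4L)
})

test_that("the tissue-fraction rule discards empty patches", {
  g <- volume_grid(c(32, 32, 32))
  mask <- array(0, g$shape)
  chi <- susceptibility_map(array(0, g$shape), g, mask)
  ch <- array(0, c(g$shape, 1))
  ps <- extract_patches(ch, chi, patch_size = 16, overlap_fraction = 0.5)
  expect_equal(length(ps), 0L)
  # a mask filling exactly 10 % of one corner patch region is kept there
  mask2 <- array(0, g$shape)
  mask2[1:16, 1:16, 1:2] <- 1   # 2/16 = 12.5 % of a 16^3 patch
  chi2 <- susceptibility_map(array(0, g$shape), g, mask2)
  ps2 <- extract_patches(ch, chi2, patch_size = 16, overlap_fraction = 0,
                         tissue_fraction_min = 0.10)
  origins <- t(vapply(ps2$items, function(it) it$origin, c(0, 0, 0)))
  expect_true(all(origins[, 3] == 1))
  # patch content matches the source volume at its origin
  it <- ps2$items[[1]]
  expect_equal(it$mask, mask2[1:16, 1:16, 1:16])
  expect_error(extract_patches(ch, chi2, patch_size = 64), "exceeds")
})

test_that("patch count is deterministic and patch sets round-trip", {
  st <- tiny_training_setup(seed = 5)
  expect_identical(length(st$patches),
                   length(tiny_training_setup(seed = 5)$patches))
  tmp <- tempfile(fileext = ".rds")
  save_patches(st$patches, tmp)
  back <- load_patches(tmp)
  expect_identical(back$items[[3]]$label, st$patches$items[[3]]$label)
  unlink(tmp)
})

test_that("rotation by zero degrees is the identity up to interpolation", {
  g <- volume_grid(c(32, 32, 32))
  chi <- generate_phantom(phantom_spec(g, n_sources = 6, seed = 8))
  rot <- augment_rotation(chi, 0)
  expect_lt(max(abs(rot$chi$values - chi$values)), 1e-6)
  expect_identical(rot$chi$mask, chi$mask)
})

test_that("rotation +15 then -15 degrees approximately restores the map", {
  # smooth content: trilinear interpolation loss stays small (sharp
  # piecewise-constant edges would smear under any interpolating rotation)
  g <- volume_grid(c(32, 32, 32))
  r <- radius_from(g$shape, c(16, 16, 16))
  smooth <- exp(-(r / 6)^2) + 0.5 * exp(-(radius_from(g$shape,
                                                      c(10, 20, 14)) / 5)^2)
  chi <- susceptibility_map(smooth, g,
                            array(as.numeric(r < 14), g$shape))
  r1 <- augment_rotation(chi, 15)
  r2 <- augment_rotation(r1$chi, -15)
  core <- r < 10
  expect_lt(rel_l2(r2$chi$values[core], chi$values[core]), 0.05)
  expect_error(augment_rotation(chi, 20), "exceed")
})

test_that("rotating a centered sphere leaves its analytic field invariant", {
  g <- volume_grid(c(48, 48, 48))
  ctr <- c(24.5, 24.5, 24.5)
  chi <- sphere_phantom(g, ctr, 7, 1)
  rot <- augment_rotation(chi, 12)
  f_an <- analytic_sphere_field(g, ctr, 7, 1)
  shell <- radius_from(g$shape, ctr) > 1.5 * 7
  # rotated sphere is still the same sphere; its circular-transform field
  # matches the padded-free comparison at the same tolerance as unrotated
  f_rot <- forward_field(susceptibility_map(rot$chi$values, g), pad = 48)
  expect_lt(rel_l2(f_rot$values[shell], f_an$values[shell]), 0.06)
})

test_that("phantom-level splits are disjoint, exhaustive and seeded", {
  sp <- split_phantoms(12, ratio = c(5, 2, 5), seed = 3)
  expect_equal(length(sp$train), 5)
  expect_equal(length(sp$val), 2)
  expect_equal(length(sp$test), 5)
  all_idx <- sort(c(sp$train, sp$val, sp$test))
  expect_equal(all_idx, 1:12)
  expect_identical(sp, split_phantoms(12, ratio = c(5, 2, 5), seed = 3))
  expect_false(identical(sp, split_phantoms(12, ratio = c(5, 2, 5),
                                            seed = 4)))
})
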