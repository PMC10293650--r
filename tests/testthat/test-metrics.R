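test_that("NRMSE satisfies its closed-form identities", {
  x <- rand_volume(16, 1)
  expect_equal(nrmse(x, x), 0)
  expect_equal(nrmse(2 * x, x), 100)
  expect_equal(nrmse(x * 0, x), 100)
  expect_error(nrmse(x, x * 0), "zero norm")
  # brute force over an arbitrary mask
  set.seed(2)
  m <- array(rbinom(16^3, 1, 0.5), dim(x))
  y <- x + rand_volume(16, 3, sd = 0.2)
  manual <- 100 * sqrt(sum(((y - x)[m > 0])^2)) / sqrt(sum((x[m > 0])^2))
  expect_equal(nrmse(y, x, m), manual, tolerance = 1e-12)
})

test_that("PSNR follows its formula and the 6.02 dB doubling rule", {
  x <- rand_volume(16, 4)
  e <- rand_volume(16, 5, sd = 0.1)
  p1 <- psnr(x + e, x)
  p2 <- psnr(x + 2 * e, x)
  expect_equal(p1 - p2, 20 * log10(2), tolerance = 1e-9)
  expect_equal(psnr(x, x), 100)     # identical inputs hit the cap
  # hand-computed 3-voxel example: x = (0,1,2), pred = (0,1,1):
  # RMSE = sqrt(1/3), peak = 2 -> 20 log10(2 sqrt(3)) = 10.79 dB
  expect_equal(psnr(array(c(0, 1, 1), c(1, 1, 3)),
                    array(c(0, 1, 2), c(1, 1, 3))),
               20 * log10(2 * sqrt(3)), tolerance = 1e-9)
  expect_equal(20 * log10(2 * sqrt(3)), 10.79, tolerance = 1e-3)
  expect_error(psnr(x, x * 0 + 3), "constant")
})

test_that("HFEN annihilates constants and is linear in the perturbation", {
  x <- rand_volume(16, 6)
  expect_equal(hfen(x, x), 0)
  expect_lt(hfen(x + 5, x), 1e-8)
  # linearity: a DC-free perturbation p gives 100 ||LoG p|| / ||LoG x||
  p <- rand_volume(16, 7, sd = 0.3)
  h1 <- hfen(x + p, x)
  h2 <- hfen(x + 2 * p, x)
  expect_equal(h2, 2 * h1, tolerance = 1e-9)
  expect_error(hfen(x, array(1, dim(x)) + 0), "constant|high-frequency")
})

test_that("HFEN matches a brute-force direct LoG convolution", {
  # direct spatial convolution on a small volume, interior voxels only
  set.seed(8)
  n <- 12
  x <- array(rnorm(n^3), c(n, n, n))
  y <- x + array(rnorm(n^3, sd = 0.3), c(n, n, n))
  k <- qsmdi:::log_kernel(5, 1.5)
  direct <- function(v) {
    out <- array(0, dim(v))
    for (i in 3:(n - 2)) for (j in 3:(n - 2)) for (l in 3:(n - 2))
      out[i, j, l] <- sum(v[(i - 2):(i + 2), (j - 2):(j + 2),
                            (l - 2):(l + 2)] * k)
    out
  }
  interior <- array(FALSE, dim(x)); interior[3:(n - 2), 3:(n - 2), 3:(n - 2)] <- TRUE
  got <- hfen(y, x, mask = interior * 1, size = 5, sigma = 1.5)
  ly <- direct(y); lx <- direct(x)
  manual <- 100 * sqrt(sum((ly[interior] - lx[interior])^2)) /
    sqrt(sum(lx[interior]^2))
  expect_equal(got, manual, tolerance = 1e-9)
})

test_that("SSIM is 1 at identity, symmetric, and negative for sign flips", {
  x <- rand_volume(16, 9)
  expect_equal(ssim3d(x, x), 1)
  y <- x + rand_volume(16, 10, sd = 0.3)
  expect_equal(ssim3d(x, y), ssim3d(y, x), tolerance = 1e-9)
  expect_lt(ssim3d(y, x), 1)
  # anti-correlated pattern with (locally) zero mean scores negative:
  # the luminance term is ~1 and the structure term is ~-1
  n <- 16
  parity <- array((-1)^(outer(outer(1:n, 1:n, "+"), 1:n, "+")), c(n, n, n))
  z <- parity * (1 + 0.2 * rand_volume(n, 11))
  expect_lt(ssim3d(-z, z), 0)
})

test_that("ROI regression recovers exact linear relations", {
  x <- seq(-0.1, 0.3, length.out = 10)
  r1 <- suppressWarnings(roi_regression(x, x))
  expect_equal(r1$slope, 1, tolerance = 1e-12)
  expect_equal(r1$r_squared, 1, tolerance = 1e-12)
  r2 <- suppressWarnings(roi_regression(0.5 * x + 0.1, x))
  expect_equal(r2$slope, 0.5, tolerance = 1e-12)
  expect_equal(r2$intercept, 0.1, tolerance = 1e-12)
  expect_equal(r2$r_squared, 1, tolerance = 1e-12)
  expect_error(roi_regression(x[1:2], x[1:2]), "at least 3")
  expect_error(roi_regression(x, rep(1, 10)), "zero variance")
})

test_that("OLS slope estimates cover the truth at the nominal 95 % rate", {
  # y = 0.9 x + eps, n = 50; the analytic CI should contain 0.9 in ~95 %
  # of replicates (>= 93 % asserted over 500 seeded replicates)
  set.seed(123)
  x <- runif(50, -0.1, 0.3)
  hits <- 0L
  for (rep in 1:500) {
    y <- 0.9 * x + rnorm(50, sd = 0.05)
    fit <- roi_regression(y, x)
    se <- summary(fit$fit)$coefficients[2, 2]
    ci <- fit$slope + c(-1, 1) * qt(0.975, 48) * se
    if (ci[1] <= 0.9 && 0.9 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.93)
})

test_that("the metric report aggregates all four metrics over the mask", {
  st <- tiny_training_setup(seed = 7)
  rec <- tkd_inversion(st$field, tau = 0.2)
  rep <- metric_report(rec$values, st$chi$values, st$chi$mask)
  expect_equal(rep$nrmse_pct, nrmse(rec$values, st$chi$values, st$chi$mask))
  expect_equal(rep$ssim, ssim3d(rec$values, st$chi$values, st$chi$mask))
  expect_equal(rep$mask_voxels, sum(st$chi$mask))
  df <- as.data.frame(rep)
  expect_equal(names(df), c("hfen_pct", "nrmse_pct", "psnr_db", "ssim",
                            "mask_voxels"))
})
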