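# the compiled layer primitives against naive R convolutions and numeric
# gradients (float32 arithmetic: tolerances reflect single precision)

test_that("compiled 3x3x3 convolution matches the naive direct sum", {
  set.seed(1)
  x <- array(rnorm(5 * 6 * 4 * 2 * 2), c(5, 6, 4, 2, 2))
  w <- array(rnorm(27 * 2 * 3, sd = 0.3), c(3, 3, 3, 2, 3))
  b <- rnorm(3)
  expect_lt(max(abs(qsmdi:::.cn_conv3_fw(x, w, b) - naive_conv3(x, w, b))),
            1e-5)
  # 1x1x1 head
  w1 <- array(rnorm(2 * 3), c(1, 1, 1, 2, 3))
  expect_lt(max(abs(qsmdi:::.cn_conv3_fw(x, w1, b) -
                      naive_conv3(x, w1, b))), 1e-5)
})

test_that("convolution backward passes the numeric gradient check", {
  set.seed(2)
  x <- array(rnorm(5 * 6 * 4 * 2 * 2), c(5, 6, 4, 2, 2))
  w <- array(rnorm(27 * 2 * 3, sd = 0.3), c(3, 3, 3, 2, 3))
  b <- rnorm(3)
  loss <- function(y) sum(sin(y))
  y <- qsmdi:::.cn_conv3_fw(x, w, b)
  gr <- qsmdi:::.cn_conv3_bw(x, w, array(cos(y), dim(y)))
  gx <- numeric_grad(function(a) loss(qsmdi:::.cn_conv3_fw(a, w, b)), x)
  gw <- numeric_grad(function(a) loss(qsmdi:::.cn_conv3_fw(x, a, b)), w)
  gb <- numeric_grad(function(a) loss(qsmdi:::.cn_conv3_fw(x, w, a)), b)
  expect_lt(max(abs(gr$dx - gx)) / max(abs(gx)), 1e-2)
  expect_lt(max(abs(gr$dw - gw)) / max(abs(gw)), 1e-2)
  expect_lt(max(abs(gr$db - gb)) / max(abs(gb)), 1e-2)
})

test_that("transposed convolution upsamples 2x and is the strided adjoint", {
  set.seed(3)
  # weight of the underlying stride-2 convolution mapping cout=3 -> cin=2
  wt <- array(rnorm(27 * 3 * 2, sd = 0.3), c(3, 3, 3, 3, 2))
  bt <- rep(0, 3)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2, 1))
  y <- qsmdi:::.cn_convt3_fw(x, wt, bt)
  expect_equal(dim(y), c(8, 8, 8, 3, 1))
  # adjoint identity: <convT(x), u> = <x, conv_s2(u)> for zero bias
  u <- array(rnorm(length(y)), dim(y))
  v <- naive_conv3(u, wt, rep(0, 2), stride = 2)
  expect_lt(abs(sum(u * y) - sum(x * v)) / abs(sum(x * v)), 1e-4)
})

test_that("transposed convolution backward passes the gradient check", {
  set.seed(4)
  wt <- array(rnorm(27 * 3 * 2, sd = 0.3), c(3, 3, 3, 3, 2))
  bt <- rnorm(3)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2, 1))
  loss <- function(y) sum(sin(y))
  y <- qsmdi:::.cn_convt3_fw(x, wt, bt)
  gr <- qsmdi:::.cn_convt3_bw(x, wt, array(cos(y), dim(y)))
  gx <- numeric_grad(function(a) loss(qsmdi:::.cn_convt3_fw(a, wt, bt)), x)
  gw <- numeric_grad(function(a) loss(qsmdi:::.cn_convt3_fw(x, a, bt)), wt)
  expect_lt(max(abs(gr$dx - gx)) / max(abs(gx)), 1e-2)
  expect_lt(max(abs(gr$dw - gw)) / max(abs(gw)), 1e-2)
})

test_that("max pooling tracks argmax indices and routes gradients", {
  set.seed(5)
  x <- array(rnorm(4 * 4 * 4 * 2 * 2), c(4, 4, 4, 2, 2))
  mp <- qsmdi:::.cn_maxpool_fw(x)
  expect_equal(dim(mp$y), c(2, 2, 2, 2, 2))
  expect_equal(mp$y[1, 1, 1, 1, 1], max(x[1:2, 1:2, 1:2, 1, 1]),
               tolerance = 1e-6)
  expect_equal(mp$y[2, 1, 2, 2, 1], max(x[3:4, 1:2, 3:4, 2, 1]),
               tolerance = 1e-6)
  dy <- array(1, dim(mp$y))
  dx <- qsmdi:::.cn_maxpool_bw(dy, mp$idx, dim(x))
  # each pooling window routes exactly one unit of gradient
  expect_equal(sum(dx), length(mp$y))
  expect_true(all(dx %in% c(0, 1)))
  expect_error(qsmdi:::.cn_maxpool_fw(x[1:3, , , , , drop = FALSE]), "even")
})

test_that("batch normalization normalizes and backpropagates correctly", {
  set.seed(6)
  x <- array(rnorm(6 * 5 * 4 * 2 * 3, mean = 2, sd = 3), c(6, 5, 4, 2, 3))
  g <- runif(2, 0.5, 1.5); be <- rnorm(2)
  fw <- qsmdi:::.cn_bn_fw(x, g, be, rep(0, 2), rep(1, 2), 1e-5, 0.1, TRUE)
  # normalized activations have per-channel mean ~beta and sd ~gamma
  for (c in 1:2) {
    v <- fw$y[, , , c, ]
    expect_equal(mean(v), be[c], tolerance = 1e-4)
    # batch normalization uses the biased (population) variance
    expect_equal(sqrt(mean((v - mean(v))^2)), g[c], tolerance = 1e-3)
  }
  # running stats move toward the batch stats
  expect_equal(fw$rmean, 0.1 * fw$mean, tolerance = 1e-6)
  gr <- qsmdi:::.cn_bn_bw(x, array(cos(fw$y), dim(x)), g, fw$mean, fw$var,
                          1e-5)
  lb <- function(a) sum(sin(qsmdi:::.cn_bn_fw(a, g, be, rep(0, 2), rep(1, 2),
                                              1e-5, 0.1, TRUE)$y))
  gx <- numeric_grad(lb, x, h = 1e-2)
  expect_lt(max(abs(gr$dx - gx)) / max(abs(gx)), 2e-2)
  # inference mode uses the supplied running stats
  fw_inf <- qsmdi:::.cn_bn_fw(x, g, be, rep(1, 2), rep(4, 2), 1e-5, 0.1,
                              FALSE)
  expect_equal(fw_inf$y[1, 1, 1, 1, 1],
               g[1] * (x[1, 1, 1, 1, 1] - 1) / sqrt(4 + 1e-5) + be[1],
               tolerance = 1e-5)
})

test_that("the fused network gradients match numeric differentiation", {
  spec <- network_spec(in_channels = 2, base_channels = 2, depth = 2)
  model <- build_network(spec, seed = 9)
  # shift the normalization offsets so activations sit away from the
  # rectifier kink; keeps the finite-difference comparison clean
  for (li in seq_along(model$params))
    if (!is.null(model$params[[li]]$beta))
      model$params[[li]]$beta[] <- 3
  set.seed(10)
  x <- array(rnorm(4^3 * 2 * 2, sd = 0.5), c(4, 4, 4, 2, 2))
  loss_of <- function(params) {
    h <- qsmdi:::.net_create(model$plan, params)
    sum(sin(qsmdi:::.net_forward(h, x, TRUE)))
  }
  h <- qsmdi:::.net_create(model$plan, model$params)
  y <- qsmdi:::.net_forward(h, x, TRUE)
  qsmdi:::.net_backward(h, array(cos(y), dim(y)))
  grads <- qsmdi:::.net_get_grads(h)
  # directional derivative over all parameters: robust to single-precision
  # round-off and rectifier kinks, yet sensitive to any mis-wired layer
  shift <- function(params, dir, eps) {
    for (li in seq_along(params)) {
      if (is.null(params[[li]])) next
      for (nm in names(dir[[li]]))
        params[[li]][[nm]] <- params[[li]][[nm]] + eps * dir[[li]][[nm]]
    }
    params
  }
  for (probe in 1:3) {
    set.seed(100 + probe)
    dir <- lapply(grads, function(g) {
      if (is.null(g)) return(NULL)
      lapply(g, function(a)
        array(rnorm(length(a)), if (is.null(dim(a))) length(a) else dim(a)))
    })
    gan <- 0
    for (li in seq_along(grads)) {
      if (is.null(grads[[li]])) next
      for (nm in names(grads[[li]]))
        gan <- gan + sum(grads[[li]][[nm]] * dir[[li]][[nm]])
    }
    eps <- 1e-3
    gnum <- (loss_of(shift(model$params, dir, eps)) -
               loss_of(shift(model$params, dir, -eps))) / (2 * eps)
    expect_lt(abs(gan - gnum), 2e-2 * abs(gnum) + 1e-3)
  }
})
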