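test_that("a short training run reduces the loss and is reproducible", {
  st <- tiny_training_setup(seed = 7)
  spec <- network_spec(3, 4, 2)
  cfg <- train_config(epochs = 2, batch_size = 4, seed = 3)
  m1 <- train_network(st$patches, NULL, spec, cfg)
  expect_lt(m1$log$train_loss[2], m1$log$train_loss[1])
  m2 <- train_network(st$patches, NULL, spec, cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
  expect_error(train_network(structure(list(items = list(),
                                            patch_size = c(16, 16, 16),
                                            n_channels = 3),
                                       class = "qsm_patch_set"),
                             NULL, spec, cfg), "empty")
})

test_that("the plateau rule decays the learning rate by its factor", {
  cfg <- train_config(lr0 = 1e-3, lr_decay_factor = 0.1)
  expect_equal(cfg$lr0 * cfg$lr_decay_factor, 1e-4)
  # trigger a decay in practice: a patience of 1 with an impossible
  # min-delta forces a decay after every epoch
  st <- tiny_training_setup(seed = 7)
  cfg2 <- train_config(epochs = 4, batch_size = 4, seed = 3,
                       plateau_patience = 1, plateau_min_delta = 1)
  m <- train_network(st$patches, NULL, network_spec(3, 4, 2), cfg2)
  # epoch 1 establishes the baseline; every later epoch then triggers a decay
  expect_equal(m$log$lr, c(1e-3, 1e-3, 1e-4, 1e-5))
})

test_that("validation loss is tracked and the best parameters retained", {
  st <- tiny_training_setup(seed = 7)
  val <- extract_patches(st$channels, st$chi, patch_size = 16,
                         overlap_fraction = 0)
  cfg <- train_config(epochs = 2, batch_size = 4, seed = 3)
  m <- train_network(st$patches, val, network_spec(3, 4, 2), cfg)
  expect_equal(nrow(m$log), 2)
  expect_true(all(is.finite(m$log$val_loss)))
  expect_true(m$trained)
})

test_that("prediction honours shape, mask, padding and determinism", {
  st <- tiny_training_setup(seed = 7)
  cfg <- train_config(epochs = 2, batch_size = 4, seed = 3)
  model <- train_network(st$patches, NULL, network_spec(3, 4, 3), cfg)
  pred <- predict_qsm(model, st$field, tau = 0.3)
  expect_equal(dim(pred$values), st$grid$shape)
  expect_true(all(pred$values[st$field$mask == 0] == 0))
  pred2 <- predict_qsm(model, st$field, tau = 0.3)
  expect_identical(pred$values, pred2$values)
  # a volume not divisible by 2^(depth-1) is reflect-padded internally
  g2 <- volume_grid(c(20, 20, 20))
  chi2 <- generate_phantom(phantom_spec(g2, n_sources = 4, seed = 2))
  f2 <- forward_field(chi2, noise_sd = 0)
  pred3 <- predict_qsm(model, f2, tau = 0.3)
  expect_equal(dim(pred3$values), c(20, 20, 20))
  expect_true(all(is.finite(pred3$values)))
  # untrained models refuse to predict
  expect_error(predict_qsm(build_network(network_spec(3, 4, 2)), st$field),
               "untrained")
})

test_that("training beats the untrained network on its own data", {
  st <- tiny_training_setup(seed = 7)
  cfg <- train_config(epochs = 6, batch_size = 4, seed = 3)
  spec <- network_spec(3, 4, 2)
  model <- train_network(st$patches, NULL, spec, cfg)
  pred <- predict_qsm(model, st$field, tau = 0.3)
  err_trained <- nrmse(pred$values, st$chi$values, st$chi$mask)
  untrained <- build_network(spec, seed = 3)
  untrained$trained <- TRUE           # bypass the guard; z-stats stay unit
  untrained$norm <- model$norm
  pred0 <- predict_qsm(untrained, st$field, tau = 0.3)
  err_untrained <- nrmse(pred0$values, st$chi$values, st$chi$mask)
  expect_lt(err_trained, err_untrained)
})

test_that("patch channels must match the network specification", {
  st <- tiny_training_setup(seed = 7)
  expect_error(train_network(st$patches, NULL, network_spec(2, 4, 2),
                             train_config(epochs = 1)),
               "do not match")
  # patch size must fit the pooling ladder
  expect_error(train_network(st$patches, NULL, network_spec(3, 4, 6),
                             train_config(epochs = 1)),
               "divisible")
})
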