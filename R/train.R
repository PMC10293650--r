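#' Training configuration
#'
#' Adam with an initial learning rate of 0.001 decayed by a factor of 0.1
#' when the validation loss stops improving, batches of 8 and 160 epochs,
#' with composite-loss weights 0.5 / 1 / 0.1 (model, L1, gradient).  The
#' plateau rule fires when no relative improvement beyond `plateau_min_delta`
#' is seen for `plateau_patience` consecutive epochs.
#'
#' @param lr0 initial learning rate.
#' @param lr_decay_factor multiplicative decay on plateau.
#' @param plateau_patience epochs without improvement before decaying.
#' @param plateau_min_delta minimum relative improvement that resets the
#'   plateau counter.
#' @param batch_size samples per optimization step.
#' @param epochs training epochs.
#' @param loss_weights numeric triple `(model, l1, gradient)`.
#' @param seed seed controlling initialization and batch shuffling.
#' @return An object of class `qsm_train_config`.
#' @export
train_config <- function(lr0 = 0.001, lr_decay_factor = 0.1,
                         plateau_patience = 10, plateau_min_delta = 1e-4,
                         batch_size = 8, epochs = 160,
                         loss_weights = c(model = 0.5, l1 = 1, gradient = 0.1),
                         seed = 1L) {
  if (epochs < 1) stop("'epochs' must be at least 1")
  if (any(loss_weights < 0)) stop("loss weights must be non-negative")
  structure(
    list(lr0 = lr0, lr_decay_factor = lr_decay_factor,
         plateau_patience = as.integer(plateau_patience),
         plateau_min_delta = plateau_min_delta,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         loss_weights = loss_weights, seed = as.integer(seed)),
    class = "qsm_train_config"
  )
}

# stack selected patches into 5-D batch arrays (x, label, mask)
make_batch <- function(patches, idx, channel_sel = NULL) {
  p <- patches$patch_size
  it <- patches$items[idx]
  nc <- if (is.null(channel_sel)) dim(it[[1]]$channels)[4]
        else length(channel_sel)
  x <- array(0, c(p, nc, length(it)))
  lab <- array(0, c(p, 1, length(it)))
  msk <- array(0, c(p, 1, length(it)))
  for (s in seq_along(it)) {
    ch <- it[[s]]$channels
    if (!is.null(channel_sel)) ch <- ch[, , , channel_sel, drop = FALSE]
    x[, , , , s] <- ch
    lab[, , , 1, s] <- it[[s]]$label
    msk[, , , 1, s] <- it[[s]]$mask
  }
  list(x = x, label = lab, mask = msk)
}

# per-channel z-scoring statistics over the masked voxels of a patch set
norm_stats <- function(patches) {
  nc <- patches$n_channels
  sx <- numeric(nc); sx2 <- numeric(nc)
  sy <- 0; sy2 <- 0; n <- 0
  for (it in patches$items) {
    m <- it$mask > 0
    nm <- sum(m)
    if (nm == 0) next
    n <- n + nm
    for (c in seq_len(nc)) {
      v <- it$channels[, , , c][m]
      sx[c] <- sx[c] + sum(v); sx2[c] <- sx2[c] + sum(v^2)
    }
    v <- it$label[m]
    sy <- sy + sum(v); sy2 <- sy2 + sum(v^2)
  }
  if (n < 2) stop("not enough masked voxels for normalization statistics")
  in_mean <- sx / n
  in_sd <- sqrt(pmax(sx2 / n - in_mean^2, 0))
  out_mean <- sy / n
  out_sd <- sqrt(max(sy2 / n - out_mean^2, 0))
  if (any(in_sd <= 0) || out_sd <= 0)
    stop("degenerate normalization statistics (zero variance)")
  list(in_mean = in_mean, in_sd = in_sd, out_mean = out_mean, out_sd = out_sd)
}

normalize_batch <- function(b, norm) {
  for (c in seq_len(dim(b$x)[4]))
    b$x[, , , c, ] <- (b$x[, , , c, ] - norm$in_mean[c]) / norm$in_sd[c]
  b$label <- (b$label - norm$out_mean) / norm$out_sd
  b
}

#' Train the dipole-inversion network
#'
#' Mini-batch Adam training of the encoder-decoder network on a patch set,
#' with the composite model/L1/gradient loss evaluated in the z-scored
#' space (statistics taken from the training set and stored in the model).
#' The validation loss (training loss when no validation set is given)
#' drives the learning-rate plateau rule; the parameters with the best
#' validation loss are retained.
#'
#' @param train a `qsm_patch_set` of training patches.
#' @param val optional `qsm_patch_set` for validation.
#' @param spec a [network_spec()]; its `in_channels` must match the patches.
#' @param config a [train_config()].
#' @param verbose print per-epoch losses.
#' @return A trained `qsm_model` with the training log (`$log`: epoch,
#'   train_loss, val_loss, lr).
#' @export
train_network <- function(train, val = NULL, spec = network_spec(),
                          config = train_config(), verbose = FALSE) {
  if (!inherits(train, "qsm_patch_set")) stop("'train' must be a qsm_patch_set")
  if (length(train$items) == 0) stop("empty training set")
  if (!is.null(val) && !inherits(val, "qsm_patch_set"))
    stop("'val' must be a qsm_patch_set")
  if (train$n_channels != spec$in_channels)
    stop("patch channels do not match the network specification")
  p <- train$patch_size
  if (any(p %% net_divisor(spec) != 0))
    stop(sprintf("patch size must be divisible by %d for depth %d",
                 net_divisor(spec), spec$depth))

  model <- build_network(spec, seed = config$seed)
  norm <- norm_stats(train)
  model$norm <- norm
  dk <- dipole_kernel(volume_grid(p))$values
  handle <- net_handle(model)

  n_train <- length(train$items)
  lr <- config$lr0
  best_val <- Inf
  best_params <- model$params
  stall <- 0L
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), lr = numeric())

  epoch_loss <- function(patches, training) {
    idx <- seq_along(patches$items)
    tot <- 0
    for (b in split(idx, ceiling(seq_along(idx) / config$batch_size))) {
      bt <- normalize_batch(make_batch(patches, b), norm)
      pred <- .net_forward(handle, bt$x, FALSE)
      li <- loss_batch(pred, bt$label, bt$mask, dk, config$loss_weights)
      tot <- tot + li$total * length(b)
    }
    tot / length(idx)
  }

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_train)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      tr_loss <- 0
      for (b in batches) {
        bt <- normalize_batch(make_batch(train, b), norm)
        pred <- .net_forward(handle, bt$x, TRUE)
        li <- loss_batch(pred, bt$label, bt$mask, dk, config$loss_weights,
                         grad = TRUE)
        .net_backward(handle, li$grad)
        .net_adam_step(handle, lr)
        tr_loss <- tr_loss + li$total * length(b)
      }
      tr_loss <- tr_loss / n_train
      v_loss <- if (is.null(val)) tr_loss else epoch_loss(val, FALSE)
      log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = v_loss, lr = lr))
      if (verbose)
        message(sprintf("epoch %3d  train %.5g  val %.5g  lr %.2g",
                        epoch, tr_loss, v_loss, lr))
      improved <- is.finite(v_loss) &&
        (!is.finite(best_val) ||
           v_loss < best_val * (1 - config$plateau_min_delta))
      if (improved) {
        best_val <- v_loss
        best_params <- .net_get_params(handle)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$plateau_patience) {
          lr <- lr * config$lr_decay_factor
          stall <- 0L
        }
      }
    }
  })

  model$params <- best_params
  model$log <- log
  model$config <- config
  model$trained <- TRUE
  model
}

# reflect-pad a 3-D array so each dimension is a multiple of `div`
pad_to_multiple <- function(x, div) {
  n <- dim(x)
  pad <- (div - n %% div) %% div
  if (all(pad == 0)) return(list(x = x, pad = pad))
  if (any(pad >= n))
    stop("volume too small to pad to the required divisibility")
  out <- x
  for (a in 1:3) {
    if (pad[a] == 0) next
    nn <- dim(out)
    take <- rev(seq_len(nn[a]))[2:(pad[a] + 1L)]  # reflect without the edge
    idx <- lapply(nn, seq_len)
    idx[[a]] <- take
    out2 <- array(0, nn + c(a == 1, a == 2, a == 3) * pad[a])
    base <- lapply(dim(out2), seq_len)
    base[[a]] <- seq_len(nn[a])
    out2[base[[1]], base[[2]], base[[3]]] <- out
    ext <- base
    ext[[a]] <- nn[a] + seq_len(pad[a])
    out2[ext[[1]], ext[[2]], ext[[3]]] <- out[idx[[1]], idx[[2]], idx[[3]]]
    out <- out2
  }
  list(x = out, pad = pad)
}

#' Reconstruct a susceptibility map with a trained network
#'
#' Builds the fidelity-split input channels at threshold `tau` (default 0.3),
#' z-scores them with the statistics stored in the model, reflect-pads the
#' volume to the divisibility the pooling ladder requires, runs the network
#' in inference mode, and de-normalizes; voxels outside the mask are zeroed.
#'
#' @param model a trained `qsm_model`.
#' @param field a [tissue_field()] with its brain mask.
#' @param tau fidelity threshold for the input decomposition (default 0.3).
#' @param channels channel subset matching the model's `in_channels`
#'   (default the first `in_channels` of the canonical order 1 = field,
#'   2 = high-fidelity, 3 = low-fidelity; pass explicitly for ablation
#'   variants).
#' @return A [susceptibility_map()].
#' @export
predict_qsm <- function(model, field, tau = 0.3, channels = NULL) {
  if (!inherits(model, "qsm_model")) stop("'model' must be a qsm_model")
  if (!model$trained)
    stop("the model is untrained; call train_network() first")
  if (!inherits(field, "qsm_field")) stop("'field' must be a qsm_field")
  if (is.null(channels)) channels <- seq_len(model$spec$in_channels)
  if (length(channels) != model$spec$in_channels)
    stop("'channels' must match the model's input channel count")
  kern <- dipole_kernel(field$grid)
  masks <- fidelity_masks(kern, tau)
  ch <- assemble_channels(field, masks, channels)
  div <- net_divisor(model$spec)
  nc <- dim(ch)[4]
  padded <- vector("list", nc)
  for (c in seq_len(nc)) {
    pc <- pad_to_multiple(ch[, , , c], div)
    padded[[c]] <- (pc$x - model$norm$in_mean[c]) / model$norm$in_sd[c]
  }
  np <- dim(padded[[1]])
  x <- array(0, c(np, nc, 1))
  for (c in seq_len(nc)) x[, , , c, 1] <- padded[[c]]
  handle <- net_handle(model)
  pred <- .net_forward(handle, x, FALSE)
  .net_release_cache(handle)
  n <- field$grid$shape
  out <- pred[seq_len(n[1]), seq_len(n[2]), seq_len(n[3]), 1, 1]
  out <- (out * model$norm$out_sd + model$norm$out_mean) * field$mask
  susceptibility_map(array(out, n), field$grid, field$mask)
}
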