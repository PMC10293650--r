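#' Specify the multichannel 3D encoder-decoder network
#'
#' A U-shaped volumetric network: `depth` encoder blocks of two 3x3x3
#' convolutions each (batch normalization and a rectifier after every
#' convolution), max pooling 2x2x2 between blocks, and `depth - 1` decoder
#' blocks of one transposed 3x3x3 convolution (stride 2), a skip
#' concatenation, and two 3x3x3 convolutions; a final 1x1x1 convolution maps
#' to the single susceptibility channel.  The first block has
#' `base_channels` channels, doubled at every level.  At the reference size
#' (depth 5, base 32) the graph contains eighteen 3x3x3 convolutions, one
#' 1x1x1 convolution, four poolings, four transposed convolutions and four
#' concatenations.
#'
#' @param in_channels number of input channels (1, 2 or 3).
#' @param base_channels channels of the first block (default 32).
#' @param depth number of encoder blocks including the bottleneck
#'   (default 5); input volumes must be divisible by `2^(depth - 1)`.
#' @return An object of class `qsm_network_spec`.
#' @export
network_spec <- function(in_channels = 3, base_channels = 32, depth = 5) {
  in_channels <- as.integer(in_channels)
  if (!in_channels %in% 1:3)
    stop("'in_channels' must be 1, 2 or 3")
  if (base_channels < 1) stop("'base_channels' must be positive")
  if (depth < 2) stop("'depth' must be at least 2")
  structure(
    list(in_channels = in_channels, base_channels = as.integer(base_channels),
         depth = as.integer(depth), convs_per_block = 2L),
    class = "qsm_network_spec"
  )
}

#' @export
print.qsm_network_spec <- function(x, ...) {
  pl <- unet_plan(x)
  ops <- vapply(pl, function(l) l$op, "")
  cat(sprintf(
    paste0("<qsm_network_spec> in_channels %d, base %d, depth %d ",
           "(%d conv 3^3, %d conv 1^3, %d pool, %d transposed, %d concat)\n"),
    x$in_channels, x$base_channels, x$depth,
    sum(ops == "conv3"), sum(ops == "conv1"), sum(ops == "pool"),
    sum(ops == "convt"), sum(ops == "concat")
  ))
  invisible(x)
}

# layer program executed by the C++ engine: a linear op sequence over one
# current tensor plus numbered skip slots
unet_plan <- function(spec) {
  stopifnot(inherits(spec, "qsm_network_spec"))
  d <- spec$depth
  ch <- spec$base_channels * 2L^(seq_len(d) - 1L)
  plan <- list()
  add <- function(...) plan[[length(plan) + 1L]] <<- list(...)
  conv_bn_relu <- function(ci, co) {
    add(op = "conv3", cin = ci, cout = co)
    add(op = "bn", c = co)
    add(op = "relu")
  }
  cur <- spec$in_channels
  for (b in seq_len(d)) {
    conv_bn_relu(cur, ch[b]); cur <- ch[b]
    conv_bn_relu(cur, ch[b])
    if (b < d) {
      add(op = "save", slot = b)
      add(op = "pool")
    }
  }
  for (b in rev(seq_len(d - 1L))) {
    add(op = "convt", cin = cur, cout = ch[b])
    add(op = "bn", c = ch[b])
    add(op = "relu")
    cur <- ch[b]
    add(op = "concat", slot = b)
    conv_bn_relu(cur + ch[b], ch[b]); cur <- ch[b]
    conv_bn_relu(cur, ch[b])
  }
  add(op = "conv1", cin = cur, cout = 1L)
  plan
}

#' Summarize the layer graph of a network specification
#'
#' @param spec a [network_spec()].
#' @return A data frame with one row per layer (`op`, `cin`, `cout`,
#'   `n_params`).
#' @export
network_layers <- function(spec) {
  pl <- unet_plan(spec)
  rows <- lapply(pl, function(l) {
    np <- switch(l$op,
      conv3 = 27L * l$cin * l$cout + l$cout,
      conv1 = l$cin * l$cout + l$cout,
      convt = 27L * l$cin * l$cout + l$cout,
      bn = 2L * l$c,
      0L
    )
    data.frame(
      op = l$op,
      cin = if (!is.null(l$cin)) l$cin else NA_integer_,
      cout = if (!is.null(l$cout)) l$cout else if (!is.null(l$c)) l$c
             else NA_integer_,
      n_params = np
    )
  })
  do.call(rbind, rows)
}

# He (variance-scaling) initialization of all parameters; a deterministic
# function of (spec, seed)
unet_init <- function(spec, seed = 1L) {
  plan <- unet_plan(spec)
  with_seed(seed, lapply(plan, function(l) {
    switch(l$op,
      conv3 = {
        fan <- 27 * l$cin
        list(w = array(rnorm(27 * l$cin * l$cout, sd = sqrt(2 / fan)),
                       c(3, 3, 3, l$cin, l$cout)),
             b = rep(0, l$cout))
      },
      conv1 = list(
        w = array(rnorm(l$cin * l$cout, sd = sqrt(2 / l$cin)),
                  c(1, 1, 1, l$cin, l$cout)),
        b = rep(0, l$cout)
      ),
      convt = {
        fan <- 27 * l$cout
        list(w = array(rnorm(27 * l$cout * l$cin, sd = sqrt(2 / fan)),
                       c(3, 3, 3, l$cout, l$cin)),
             b = rep(0, l$cout))
      },
      bn = list(gamma = rep(1, l$c), beta = rep(0, l$c),
                rmean = rep(0, l$c), rvar = rep(1, l$c)),
      NULL
    )
  }))
}

#' Build an untrained model
#'
#' Instantiates the network parameters (variance-scaling initialization,
#' seeded) without training.  The result can be trained with
#' [train_network()] or used directly by [predict_qsm()] as an untrained
#' reference.
#'
#' @param spec a [network_spec()].
#' @param seed initialization seed.
#' @return An object of class `qsm_model` with `trained = FALSE`.
#' @export
build_network <- function(spec, seed = 1L) {
  if (!inherits(spec, "qsm_network_spec"))
    stop("'spec' must be a qsm_network_spec")
  structure(
    list(spec = spec, plan = unet_plan(spec),
         params = unet_init(spec, seed),
         norm = list(in_mean = rep(0, spec$in_channels),
                     in_sd = rep(1, spec$in_channels),
                     out_mean = 0, out_sd = 1),
         log = NULL, config = NULL, trained = FALSE, init_seed = seed),
    class = "qsm_model"
  )
}

#' @export
print.qsm_model <- function(x, ...) {
  npar <- sum(network_layers(x$spec)$n_params)
  cat(sprintf(
    "<qsm_model> %s, in_channels %d, base %d, depth %d, %d parameters\n",
    if (x$trained) "trained" else "untrained",
    x$spec$in_channels, x$spec$base_channels, x$spec$depth, npar
  ))
  if (!is.null(x$log))
    cat(sprintf("  %d epochs logged, final val loss %.5g\n",
                nrow(x$log), x$log$val_loss[nrow(x$log)]))
  invisible(x)
}

# instantiate the C++ network handle for a model
net_handle <- function(model) {
  .net_create(model$plan, model$params)
}

# forward one batch (5-D array) through a handle
net_forward <- function(handle, x, training = FALSE) {
  .net_forward(handle, x, training)
}

# required spatial divisibility of the inputs
net_divisor <- function(spec) 2L^(spec$depth - 1L)
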