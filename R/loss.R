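# Reference implementations of the finite-difference operator pair used by
# the gradient loss; the training path evaluates the same operators in the
# compiled one-pass kernel (.cn_loss_terms).
# forward finite difference along one spatial axis with replicate boundary
# (the last-slice difference is 0); works for 3-D patches and 5-D batches
fwd_diff <- function(x, axis) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  lo <- hi <- idx
  lo[[axis]] <- seq_len(d[axis] - 1L)
  hi[[axis]] <- lo[[axis]] + 1L
  out <- array(0, d)
  sub <- do.call(`[`, c(list(x), hi, list(drop = FALSE))) -
    do.call(`[`, c(list(x), lo, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), lo, list(sub)))
}

# adjoint of fwd_diff: d(sum v * fwd_diff(x))/dx puts +v at i+1 and -v at i
fwd_diff_adj <- function(v, axis) {
  d <- dim(v)
  idx <- lapply(d, seq_len)
  lo <- hi <- idx
  lo[[axis]] <- seq_len(d[axis] - 1L)
  hi[[axis]] <- lo[[axis]] + 1L
  vlo <- do.call(`[`, c(list(v), lo, list(drop = FALSE)))
  out <- array(0, d)
  out <- do.call(`[<-`, c(list(out), hi, list(vlo)))
  cur <- do.call(`[`, c(list(out), lo, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), lo, list(cur - vlo)))
}

#' Composite training loss
#'
#' The weighted sum of three terms, each a masked mean over the patch:
#' \itemize{
#'   \item model loss: `mean |d (*) pred - d (*) label|`, the L1 difference
#'     after forward dipole convolution, anchoring the prediction to the
#'     measurement physics;
#'   \item L1 loss: `mean |pred - label|`, the voxel-wise difference;
#'   \item gradient loss: `mean sum_axes | |grad pred| - |grad label| |`
#'     with forward finite differences, an edge-preservation term.
#' }
#' Default weights are 0.5, 1 and 0.1.  For batches the per-sample losses
#' are averaged.
#'
#' @param pred,label 3-D arrays (one patch) or 5-D batches
#'   `(nx, ny, nz, 1, n)`.
#' @param mask binary array of the same shape.
#' @param kernel a [dipole_kernel()] on the patch grid, or its `values`
#'   array.
#' @param weights numeric triple `(model, l1, gradient)`.
#' @param grad if `TRUE`, also return the gradient of the total loss with
#'   respect to `pred`.
#' @return A list with `total`, the three components, and (optionally)
#'   `grad`.
#' @export
composite_loss <- function(pred, label, mask, kernel,
                           weights = c(model = 0.5, l1 = 1, gradient = 0.1),
                           grad = FALSE) {
  dvals <- if (inherits(kernel, "qsm_kernel")) kernel$values else kernel
  if (length(weights) != 3 || any(weights < 0))
    stop("'weights' must be three non-negative numbers")
  if (!all(dim(pred) == dim(label)) || !all(dim(pred) == dim(mask)))
    stop("'pred', 'label' and 'mask' shapes differ")
  if (!all(is.finite(pred)) || !all(is.finite(label)))
    stop("non-finite values in 'pred' or 'label'")
  three_d <- length(dim(pred)) == 3
  if (three_d) {
    dims <- c(dim(pred), 1, 1)
    out <- loss_batch(array(pred, dims), array(label, dims),
                      array(mask, dims), dvals, weights, grad)
    if (grad) out$grad <- array(out$grad, dim(pred))
    return(out)
  }
  if (length(dim(pred)) != 5)
    stop("'pred' must be a 3-D patch or a 5-D batch")
  loss_batch(pred, label, mask, dvals, weights, grad)
}

# batch implementation over (nx, ny, nz, 1, n) arrays; vectorized over the
# batch except for the per-sample transforms of the model term
loss_batch <- function(pred, label, mask, dvals, weights, grad = FALSE) {
  d <- dim(pred)
  if (!all(d[1:3] == dim(dvals)))
    stop("'kernel' does not match the patch shape")
  B <- d[5]
  nv <- prod(d[1:4])
  # L1 and gradient terms (and their weighted gradient contribution) in one
  # compiled pass; the spectral model term needs the FFT and stays here
  terms <- .cn_loss_terms(pred, label, mask, weights[2], weights[3], grad)
  S <- terms$S
  diffv <- pred - label
  r <- array(0, d)
  for (s in seq_len(B))
    r[, , , 1, s] <- Re(ifft3(dvals * fft3(array(diffv[, , , 1, s], d[1:3]))))
  l_model <- colSums(matrix(abs(r) * mask, nv, B)) / S
  out <- list(
    total = mean(weights[1] * l_model + weights[2] * terms$l1 +
                   weights[3] * terms$grad),
    model = mean(l_model), l1 = mean(terms$l1), gradient = mean(terms$grad)
  )
  if (grad) {
    g <- terms$g
    ms <- mask * sign(r)
    # the dipole filter is real and k -> -k symmetric, hence self-adjoint
    for (s in seq_len(B))
      g[, , , 1, s] <- g[, , , 1, s] + weights[1] *
        Re(ifft3(dvals * fft3(array(ms[, , , 1, s], d[1:3])))) / (S[s] * B)
    out$grad <- g
  }
  out
}
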