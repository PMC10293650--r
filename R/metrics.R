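# values of a map-like object or plain array
field_values <- function(x) {
  if (is.list(x) && !is.null(x$values)) x$values else x
}

check_metric_inputs <- function(pred, ref, mask) {
  pred <- field_values(pred); ref <- field_values(ref)
  if (!all(dim(pred) == dim(ref)))
    stop("'pred' and 'ref' shapes differ")
  if (is.null(mask)) mask <- array(1, dim(ref))
  if (!all(dim(mask) == dim(ref))) stop("'mask' does not match the volumes")
  if (sum(mask) == 0) stop("empty mask")
  list(pred = pred, ref = ref, mask = mask > 0)
}

#' Normalized root-mean-square error (percent)
#'
#' `100 * ||pred - ref|| / ||ref||` over the mask voxels.
#'
#' @param pred,ref 3-D arrays or map objects on the same grid.
#' @param mask binary array (default: all voxels).
#' @return NRMSE in percent.
#' @export
nrmse <- function(pred, ref, mask = NULL) {
  z <- check_metric_inputs(pred, ref, mask)
  refn <- sqrt(sum(z$ref[z$mask]^2))
  if (refn == 0) stop("reference has zero norm within the mask")
  100 * sqrt(sum((z$pred[z$mask] - z$ref[z$mask])^2)) / refn
}

#' Peak signal-to-noise ratio (dB)
#'
#' `20 log10(peak / RMSE)` with `peak = max(ref) - min(ref)` within the mask.
#' Identical volumes report the cap.
#'
#' @inheritParams nrmse
#' @param cap ceiling returned for identical inputs (default 100 dB).
#' @return PSNR in dB.
#' @export
psnr <- function(pred, ref, mask = NULL, cap = 100) {
  z <- check_metric_inputs(pred, ref, mask)
  rv <- z$ref[z$mask]
  peak <- max(rv) - min(rv)
  if (peak == 0) stop("constant reference within the mask")
  rmse <- sqrt(mean((z$pred[z$mask] - rv)^2))
  if (rmse == 0) return(cap)
  min(20 * log10(peak / rmse), cap)
}

# replicate-extend a volume by the kernel half-width, convolve, crop: edge
# voxels then see a constant extension, so zero-sum kernels annihilate
# constants everywhere (not only in the interior)
fft_filter_replicate <- function(x, kern) {
  n <- dim(x); h <- (dim(kern) - 1L) %/% 2L
  ix <- pmin(pmax(seq_len(n[1] + 2 * h[1]) - h[1], 1L), n[1])
  iy <- pmin(pmax(seq_len(n[2] + 2 * h[2]) - h[2], 1L), n[2])
  iz <- pmin(pmax(seq_len(n[3] + 2 * h[3]) - h[3], 1L), n[3])
  ext <- fft_filter_same(x[ix, iy, iz], kern)
  ext[h[1] + seq_len(n[1]), h[2] + seq_len(n[2]), h[3] + seq_len(n[3])]
}

# linear "same" convolution of a 3-D array with an odd-sized kernel via
# zero-padded FFTs
fft_filter_same <- function(x, kern) {
  n <- dim(x); kn <- dim(kern)
  if (any(kn %% 2 == 0)) stop("kernel dimensions must be odd")
  N <- n + kn - 1L
  xp <- array(0, N); xp[seq_len(n[1]), seq_len(n[2]), seq_len(n[3])] <- x
  kp <- array(0, N); kp[seq_len(kn[1]), seq_len(kn[2]), seq_len(kn[3])] <- kern
  full <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) /
    prod(N)
  h <- (kn - 1L) %/% 2L
  full[h[1] + seq_len(n[1]), h[2] + seq_len(n[2]), h[3] + seq_len(n[3])]
}

# 3-D Laplacian-of-Gaussian kernel, zero-sum
log_kernel <- function(size = 15, sigma = 1.5) {
  half <- (size - 1) / 2
  ax <- seq(-half, half)
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  g <- exp(-r2 / (2 * sigma^2))
  g <- g / sum(g)
  h <- g * (r2 - 3 * sigma^2) / sigma^4
  h - mean(h)
}

#' High-frequency error norm (percent)
#'
#' Relative L2 error after filtering both volumes with a 3-D
#' Laplacian-of-Gaussian (15^3 kernel, sigma 1.5, the de-facto standard of
#' the QSM reconstruction-challenge literature):
#' `100 * ||LoG(pred) - LoG(ref)|| / ||LoG(ref)||` over the mask.  The
#' zero-sum kernel annihilates constant offsets.
#'
#' @inheritParams nrmse
#' @param size,sigma LoG filter parameters.
#' @return HFEN in percent.
#' @export
hfen <- function(pred, ref, mask = NULL, size = 15, sigma = 1.5) {
  z <- check_metric_inputs(pred, ref, mask)
  k <- log_kernel(size, sigma)
  lp <- fft_filter_replicate(z$pred, k)
  lr <- fft_filter_replicate(z$ref, k)
  refn <- sqrt(sum(lr[z$mask]^2))
  if (refn <= 1e-10 * max(sqrt(sum(z$ref[z$mask]^2)), .Machine$double.eps))
    stop("reference has no high-frequency content within the mask")
  100 * sqrt(sum((lp[z$mask] - lr[z$mask])^2)) / refn
}

# separable 3-D Gaussian window, normalized to sum 1
gaussian_window <- function(size = 11, sigma = 1.5) {
  half <- (size - 1) / 2
  ax <- seq(-half, half)
  g1 <- exp(-ax^2 / (2 * sigma^2))
  w <- outer(outer(g1, g1), g1)
  w / sum(w)
}

#' Structural similarity index for volumes
#'
#' Mean local SSIM over the mask with the standard constants (K1 = 0.01,
#' K2 = 0.03) and an isotropic Gaussian window (11^3, sigma 1.5).  The
#' dynamic range defaults to the masked value range across both volumes,
#' which keeps the measure symmetric in its arguments; pass `data_range`
#' to anchor it to the reference alone.
#'
#' @inheritParams nrmse
#' @param K1,K2 stability constants.
#' @param size,sigma window parameters.
#' @param data_range dynamic range L; `NULL` = masked range over both
#'   volumes.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim3d <- function(pred, ref, mask = NULL, K1 = 0.01, K2 = 0.03,
                   size = 11, sigma = 1.5, data_range = NULL) {
  z <- check_metric_inputs(pred, ref, mask)
  rv <- z$ref[z$mask]
  if (max(rv) == min(rv)) stop("constant reference within the mask")
  L <- if (is.null(data_range))
    max(max(rv), max(z$pred[z$mask])) - min(min(rv), min(z$pred[z$mask]))
  else data_range
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  w <- gaussian_window(size, sigma)
  mu1 <- fft_filter_replicate(z$pred, w)
  mu2 <- fft_filter_replicate(z$ref, w)
  s11 <- fft_filter_replicate(z$pred^2, w) - mu1^2
  s22 <- fft_filter_replicate(z$ref^2, w) - mu2^2
  s12 <- fft_filter_replicate(z$pred * z$ref, w) - mu1 * mu2
  smap <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(smap[z$mask])
}

#' Per-ROI linear regression against a reference
#'
#' Ordinary least squares of per-ROI mean susceptibilities of a method
#' against the reference (e.g. deep-gray-matter ROIs against a gold-standard
#' reconstruction): slope, intercept and R-squared.
#'
#' @param values_method numeric vector of per-ROI means from the method.
#' @param values_reference matching vector from the reference.
#' @return An object of class `qsm_roi_regression` with `slope`,
#'   `intercept`, `r_squared` and `n`.
#' @export
roi_regression <- function(values_method, values_reference) {
  if (length(values_method) != length(values_reference))
    stop("input lengths differ")
  if (length(values_method) < 3)
    stop("at least 3 paired observations are required")
  if (stats::var(values_reference) == 0)
    stop("zero variance in the reference values")
  fit <- stats::lm(values_method ~ values_reference)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared, n = length(values_method),
         fit = fit),
    class = "qsm_roi_regression"
  )
}

#' @export
print.qsm_roi_regression <- function(x, ...) {
  cat(sprintf(
    "<qsm_roi_regression> slope %.4f, intercept %.4f, R^2 %.4f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n
  ))
  invisible(x)
}

#' Full metric report for a reconstruction
#'
#' HFEN, NRMSE (both percent), PSNR (dB) and SSIM of a reconstruction
#' against a reference, all restricted to the mask.
#'
#' @param pred reconstructed map (array or `qsm_chi`).
#' @param ref reference map.
#' @param mask binary array; defaults to the reference's mask when it is a
#'   map object.
#' @return An object of class `qsm_metric_report`.
#' @export
metric_report <- function(pred, ref, mask = NULL) {
  if (is.null(mask) && is.list(ref) && !is.null(ref$mask)) mask <- ref$mask
  structure(
    list(
      hfen_pct = hfen(pred, ref, mask),
      nrmse_pct = nrmse(pred, ref, mask),
      psnr_db = psnr(pred, ref, mask),
      ssim = ssim3d(pred, ref, mask),
      mask_voxels = if (is.null(mask)) length(field_values(ref))
                    else sum(mask > 0)
    ),
    class = "qsm_metric_report"
  )
}

#' @export
print.qsm_metric_report <- function(x, ...) {
  cat(sprintf(
    "<qsm_metric_report> HFEN %.2f%%  NRMSE %.2f%%  PSNR %.2f dB  SSIM %.4f (%d voxels)\n",
    x$hfen_pct, x$nrmse_pct, x$psnr_db, x$ssim, x$mask_voxels
  ))
  invisible(x)
}

#' @export
as.data.frame.qsm_metric_report <- function(x, ...) {
  data.frame(hfen_pct = x$hfen_pct, nrmse_pct = x$nrmse_pct,
             psnr_db = x$psnr_db, ssim = x$ssim,
             mask_voxels = x$mask_voxels)
}
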