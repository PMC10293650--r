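#' Truncated k-space division (TKD)
#'
#' Classical training-free dipole inversion: divide the field spectrum by the
#' dipole kernel wherever |D(k)| exceeds the threshold, and stabilize the
#' ill-conditioned region by clamping the divisor.  The default
#' sign-preserving variant divides by `tau * sign(D)` where
#' `0 < |D| <= tau`; `mode = "zero"` hard-truncates those frequencies
#' instead.  The k = 0 coefficient is set to zero (the mean susceptibility is
#' not recoverable from the demeaned field).
#'
#' @param field a [tissue_field()].
#' @param kernel a [dipole_kernel()] on the same grid; built on the fly when
#'   `NULL`.
#' @param tau truncation threshold in (0, 2/3].
#' @param mode `"clamp"` (default) or `"zero"`.
#' @return A [susceptibility_map()] (masked by the field's mask).
#' @examples
#' g <- volume_grid(c(16, 16, 16))
#' f <- tissue_field(array(0, g$shape), g)
#' chi <- tkd_inversion(f, tau = 0.2)   # zero map
#' @export
tkd_inversion <- function(field, kernel = NULL, tau = 0.2,
                          mode = c("clamp", "zero")) {
  if (!inherits(field, "qsm_field")) stop("'field' must be a qsm_field")
  if (is.null(kernel)) kernel <- dipole_kernel(field$grid)
  if (!inherits(kernel, "qsm_kernel")) stop("'kernel' must be a qsm_kernel")
  stop_if_grid_mismatch(field$grid, kernel$grid, "'field' and 'kernel'")
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) ||
      tau <= 0 || tau > 2 / 3)
    stop("'tau' must lie in (0, 2/3]")
  mode <- match.arg(mode)
  d <- kernel$values
  inv <- array(0, dim(d))
  high <- abs(d) > tau
  inv[high] <- 1 / d[high]
  low <- !high & d != 0
  if (mode == "clamp") inv[low] <- 1 / (tau * sign(d[low]))
  # d == 0 bins (including DC) stay at zero
  chi_hat <- Re(ifft3(inv * fft3(field$values)))
  susceptibility_map(chi_hat * field$mask, field$grid, field$mask)
}
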