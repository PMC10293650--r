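#' Experiment harnesses over threshold and channel settings
#'
#' `run_threshold_sweep()` trains and evaluates one matched model per
#' fidelity threshold; `run_channel_ablation()` does the same per
#' input-channel subset at a fixed threshold.  Every setting sees identical
#' synthetic data (phantoms, fields, splits) and an identical training
#' budget, so the rows differ only in the setting under study.  Each row
#' reports mean and standard deviation of HFEN, NRMSE, PSNR and SSIM over
#' the test phantoms (sd is 0 with a single test phantom).
#'
#' The defaults are deliberately desk-scale (small phantoms, a reduced
#' network, few epochs): the harness reproduces the *procedure* of a
#' threshold sweep / channel ablation, not any particular published
#' numbers.  Scale up `n_split`, `grid_n`, `spec` and `config` for real
#' experiments.
#'
#' @param taus thresholds to sweep.
#' @param channel_sets list of channel subsets (in the canonical order
#'   1 = field, 2 = high-fidelity, 3 = low-fidelity).
#' @param tau fixed threshold for the ablation.
#' @param n_split integer triple: train / validation / test phantom counts.
#' @param grid_n edge length of the cubic phantom grid.
#' @param patch_size patch edge length.
#' @param overlap_fraction patch overlap.
#' @param base_channels,depth reduced network size.
#' @param config a [train_config()] (use few epochs for desk-scale runs).
#' @param noise_sd field noise level (ppm).
#' @param n_sources sources per phantom.
#' @param seed master seed; phantom seeds and the split derive from it.
#' @return A data frame with one row per setting and mean/sd columns for the
#'   four metrics.
#' @export
run_threshold_sweep <- function(taus = seq(0.1, 0.5, by = 0.1),
                                channel_sets = NULL,
                                n_split = c(2, 1, 1), grid_n = 32,
                                patch_size = 16, overlap_fraction = 0.5,
                                base_channels = 4, depth = 2,
                                config = train_config(epochs = 6,
                                                      batch_size = 4),
                                noise_sd = 0.005, n_sources = 12,
                                seed = 1L) {
  settings <- lapply(taus, function(t) list(tau = t, channels = 1:3))
  labels <- sprintf("%.1f", taus)
  out <- run_inversion_experiment(settings, n_split, grid_n, patch_size,
                                  overlap_fraction, base_channels, depth,
                                  config, noise_sd, n_sources, seed)
  cbind(data.frame(threshold = labels), out)
}

#' @rdname run_threshold_sweep
#' @export
run_channel_ablation <- function(channel_sets = list(c(1, 2), c(1, 3),
                                                     c(2, 3), c(1, 2, 3)),
                                 tau = 0.3,
                                 n_split = c(2, 1, 1), grid_n = 32,
                                 patch_size = 16, overlap_fraction = 0.5,
                                 base_channels = 4, depth = 2,
                                 config = train_config(epochs = 6,
                                                       batch_size = 4),
                                 noise_sd = 0.005, n_sources = 12,
                                 seed = 1L) {
  settings <- lapply(channel_sets, function(ch)
    list(tau = tau, channels = as.integer(ch)))
  labels <- vapply(channel_sets, function(ch)
    paste(ch, collapse = " and "), "")
  out <- run_inversion_experiment(settings, n_split, grid_n, patch_size,
                                  overlap_fraction, base_channels, depth,
                                  config, noise_sd, n_sources, seed)
  cbind(data.frame(channels = labels), out)
}

# shared machinery: one trained model per setting on identical data
run_inversion_experiment <- function(settings, n_split, grid_n, patch_size,
                                     overlap_fraction, base_channels, depth,
                                     config, noise_sd, n_sources, seed) {
  n_tot <- sum(n_split)
  grid <- volume_grid(rep(grid_n, 3))
  cases <- lapply(seq_len(n_tot), function(i) {
    chi <- generate_phantom(phantom_spec(grid, n_sources = n_sources,
                                         seed = seed * 1000L + i))
    field <- forward_field(chi, noise_sd = noise_sd,
                           seed = seed * 1000L + i)
    list(chi = chi, field = field)
  })
  split <- split_phantoms(n_tot, ratio = n_split, seed = seed)
  kern <- dipole_kernel(grid)

  rows <- lapply(settings, function(st) {
    masks <- fidelity_masks(kern, st$tau)
    patch_sets <- lapply(cases, function(cs) {
      ch <- assemble_channels(cs$field, masks, st$channels)
      extract_patches(ch, cs$chi, patch_size = patch_size,
                      overlap_fraction = overlap_fraction)
    })
    pool <- function(idx) {
      ps <- patch_sets[[idx[1]]]
      ps$items <- do.call(c, lapply(idx, function(i) patch_sets[[i]]$items))
      ps
    }
    spec <- network_spec(length(st$channels), base_channels, depth)
    model <- train_network(pool(split$train),
                           if (length(split$val)) pool(split$val) else NULL,
                           spec, config)
    reports <- lapply(split$test, function(i) {
      pred <- predict_qsm(model, cases[[i]]$field, tau = st$tau,
                          channels = st$channels)
      as.data.frame(metric_report(pred$values, cases[[i]]$chi$values,
                                  cases[[i]]$chi$mask))
    })
    rep_df <- do.call(rbind, reports)
    sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
    data.frame(
      hfen_mean = mean(rep_df$hfen_pct), hfen_sd = sd0(rep_df$hfen_pct),
      nrmse_mean = mean(rep_df$nrmse_pct), nrmse_sd = sd0(rep_df$nrmse_pct),
      psnr_mean = mean(rep_df$psnr_db), psnr_sd = sd0(rep_df$psnr_db),
      ssim_mean = mean(rep_df$ssim), ssim_sd = sd0(rep_df$ssim)
    )
  })
  do.call(rbind, rows)
}

#' Write a harness results table as CSV
#'
#' @param results data frame from [run_threshold_sweep()] or
#'   [run_channel_ablation()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_results_table <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
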