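# qsmdi — QSM dipole inversion with frequency-fidelity decomposition

Quantitative susceptibility mapping (QSM) reconstructs the tissue magnetic
susceptibility χ (in ppm of B0) from the MRI-measured local field
perturbation. The two are linked in k-space by the unit dipole response

    B(k) = D(k) X(k) + N(k),      D(k) = 1/3 − (k·b̂0)² / |k|²,

which vanishes on the magic-angle cone (cos²θ = 1/3): the inversion is
ill-posed, and naive division amplifies noise into cone-aligned streaking
artifacts. This package is a toolkit for the dipole-inversion step built
around a *frequency-fidelity decomposition*: thresholding |D(k)| at τ
splits the tissue field into a high-fidelity component (strongly encoded by
the measurement) and a low-fidelity component (weakly encoded, noise
dominated), and a multichannel 3-D encoder–decoder network receives the
original field plus both components as separate channels, so it can treat
well-conditioned and ill-conditioned spectral content differently.

The package provides, in idiomatic R with a compiled single-precision
convolution engine:

- the magnetostatic forward model (`dipole_kernel()`, `forward_field()`)
  with an analytic uniform-sphere oracle (`analytic_sphere_field()`);
- the fidelity split (`fidelity_masks()`, `decompose_field()`,
  `assemble_channels()`);
- synthetic susceptibility phantoms with hemorrhage-like lesions
  (`generate_phantom()`, `insert_lesion()`, `simulate_hemorrhage_case()`);
- the training pipeline: overlapping patch extraction with a tissue-fraction
  rule (`extract_patches()`) and rotation augmentation
  (`augment_rotation()`);
- the multichannel 3-D U-shaped network with a composite
  physics/L1/gradient loss, Adam, and learning-rate plateau decay
  (`network_spec()`, `train_network()`, `predict_qsm()`,
  `composite_loss()`);
- truncated k-space division as the classical training-free baseline
  (`tkd_inversion()`);
- evaluation: HFEN, NRMSE, PSNR, SSIM and ROI regression
  (`metric_report()`, `roi_regression()`);
- experiment harnesses over the threshold and the channel subsets
  (`run_threshold_sweep()`, `run_channel_ablation()`).

NIfTI I/O (`read_volume()`, `write_volume()`) uses RNifti; a thin
command-line front end with `simulate` / `decompose` / `tkd` / `train` /
`predict` / `evaluate` subcommands ships in `inst/cli/qsmdi`.

## Worked example

Simulate a phantom, invert its noisy field with TKD, and score the result:

```r
library(qsmdi)

grid  <- volume_grid(c(64, 64, 64))                      # 1 mm isotropic
chi   <- generate_phantom(phantom_spec(grid, n_sources = 40, seed = 42))
field <- forward_field(chi, noise_sd = 0.005, seed = 42)
chi
#> <qsm_chi> 64 x 64 x 64, chi in [-0.315, 0.435] ppm over 74152 mask voxels
field
#> <qsm_field> 64 x 64 x 64, field in [-0.144, 0.138] ppm over 74152 mask voxels

kern  <- dipole_kernel(grid)
kern
#> <qsm_kernel> 64 x 64 x 64, D(k) in [-0.6667, 0.3333], D(0) = 0
fidelity_masks(kern, 0.3)
#> <qsm_fidelity_masks> tau = 0.3, low-fidelity fraction 0.706

rec <- tkd_inversion(field, kern, tau = 0.2)
metric_report(rec$values, chi$values, chi$mask)
#> <qsm_metric_report> HFEN 29.32%  NRMSE 42.41%  PSNR 28.79 dB  SSIM 0.5739 (74152 voxels)
```

The report reads: the truncated inversion recovers the susceptibility map
with 42 % of the reference norm left as error (the all-zero map would score
exactly 100 %), 29 % error in the high-frequency band, and moderate
structural similarity — typical for TKD on a noisy field at τ = 0.2.

Training the fidelity-split network on phantom patches follows the same
pattern (see the vignette for the full pipeline):

```r
masks   <- fidelity_masks(kern, 0.3)
chans   <- assemble_channels(field, masks)          # field, high, low
patches <- extract_patches(chans, chi, patch_size = 32, overlap_fraction = 0.66)
model   <- train_network(patches, NULL,
                         network_spec(in_channels = 3, base_channels = 8, depth = 3),
                         train_config(epochs = 16, batch_size = 8, seed = 1))
pred    <- predict_qsm(model, field, tau = 0.3)
```

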