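---
title: "Frequency-fidelity decomposition for QSM dipole inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-fidelity decomposition for QSM dipole inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsmdi)
```

## The dipole-inversion problem

Quantitative susceptibility mapping (QSM) estimates the tissue magnetic
susceptibility $\chi$ (in ppm of the main field $B_0$) from the measured
local field perturbation.  In k-space the two are related by a pointwise
product with the unit dipole response

$$B(k) = D(k)\,X(k) + N(k), \qquad
  D(k) = \frac{1}{3} - \frac{(k \cdot \hat b_0)^2}{|k|^2},$$

where $X$ and $B$ are the transforms of the susceptibility and the tissue
field and $N$ is noise.  $D$ ranges from $-2/3$ (frequencies along $B_0$)
to $1/3$ (perpendicular) and vanishes on the magic-angle cone
($\cos^2\theta = 1/3$).  Direct division $\hat X = B/D$ therefore amplifies
noise without bound near the cone, which is the source of the streaking
artifacts that plague naive inversion.

`dipole_kernel()` evaluates $D$ on the discrete FFT frequencies of the grid
(cycles/mm; only the ratio in the formula matters, so any consistent
frequency scaling gives the same kernel).  Two conventions are deliberate:

* **DC bin.** $D(0)$ is $0/0$ in the formula and is set to $0$, which
  demeans the simulated field.  The mean susceptibility is not recoverable
  from a demeaned internal field, so every inversion in the package returns
  a zero-mean-convention map.
* **Exact extremes.** $D$ is computed as $(1 - 3\,r)/3$ with
  $r = (k\cdot\hat b_0)^2/|k|^2$, so the extreme values $1/3$ and $-2/3$
  are attained exactly in floating point on axis-aligned $B_0$ grids
  (for oblique unit vectors they hold to rounding of the vector itself).

### Circular versus padded transforms

`forward_field()` computes the spectral product with the plain (circular)
FFT by default.  This is the algebraic model that truncated inversion, the
fidelity decomposition and the training loss all assume, and it makes the
synthetic pipeline exactly self-consistent: a band-limited susceptibility is
recovered from its noise-free field to floating-point precision.

A circular transform, however, also convolves a compact source with its
periodic replicas.  For *physical* simulation of isolated sources the
`pad` argument zero-pads the volume (padding by half the grid size
suppresses the wrap-around to about the voxelization error).  The analytic
uniform-sphere solution,

$$\frac{\Delta B}{B_0} =
  \frac{\Delta\chi}{3}\left(\frac{R}{r}\right)^3 (3\cos^2\theta - 1)
  \quad (r > R), \qquad 0 \quad (r < R),$$

implemented in `analytic_sphere_field()`, serves as an independent
magnetostatics oracle: on a $96^3$ grid with a radius-12 sphere the padded
forward field agrees with it to below 2 % relative $\ell_2$ error outside
$1.5R$, and the circular-transform error decreases with grid size as the
replicas recede.

## Frequency-fidelity decomposition

Thresholding $|D|$ at $\tau$ splits k-space into a *low-fidelity* region
(weakly encoded, noise-amplifying on inversion) and its *high-fidelity*
complement.  `fidelity_masks()` builds the complementary binary masks
(boundary $|D| = \tau$ and the DC bin go to the low mask — both have
$|D| \le \tau$), and `decompose_field()` applies them to a tissue field.
Because the masks partition the spectrum exactly, the two components sum
back to the input to round-off and their spectral energies satisfy
Parseval's identity; because they inherit the kernel's $k \to -k$ symmetry,
both components are real.

The inversion network receives the original field and both components as
three channels (`assemble_channels()`, canonical order: 1 = field,
2 = high-fidelity, 3 = low-fidelity).  The rationale: the network can learn
different strategies for spectral content that the measurement constrains
strongly versus content it must infer from context, instead of being left
to discover the dipole geometry on its own.  Channel subsets are supported
throughout for ablation experiments.  The default threshold is
$\tau = 0.3$, the value at which the sweep harness's quality metrics
plateau; it remains a tunable argument everywhere.

## Network, loss, and training

`network_spec()` describes a volumetric U-shaped encoder–decoder:

* `depth` encoder blocks of two $3^3$ convolutions, each followed by batch
  normalization and a rectifier; $2^3$ max pooling between blocks;
* `depth - 1` decoder stages of a $3^3$ transposed convolution (stride 2,
  also with normalization and rectifier), a skip concatenation with the
  same-resolution encoder output, and two further $3^3$ convolutions;
* a final linear $1^3$ convolution to one output channel.

The first block has `base_channels` channels, doubled per level.  At the
reference size (depth 5, base 32, three input channels) the graph has
eighteen $3^3$ convolutions, one $1^3$ convolution, four poolings, four
transposed convolutions and four concatenations, with the channel ladder
32–64–128–256–512.  Weights use variance-scaling (He) initialization from a
seeded generator; batch normalization uses $\epsilon = 10^{-5}$ and running
statistics with momentum 0.1 for inference.

Inference (`predict_qsm()`) is whole-volume: the channels are built at the
requested threshold, z-scored with training-set statistics stored in the
model, reflect-padded to the divisibility that the pooling ladder requires
($2^{\mathrm{depth}-1}$), passed through the network, un-padded,
de-normalized and masked.  No test-time patch tiling is used.

### Composite loss

Training minimizes a weighted sum of three masked means over each patch
(weights 0.5 / 1 / 0.1):

* **model loss** — $\mathrm{mean}\,|d \ast \hat\chi - d \ast \chi|$, the
  difference after forward dipole convolution.  The label's forward field
  is used as the anchor rather than the measured patch field: patches are
  cropped from a larger volume, so their measured fields contain
  contributions from sources outside the crop, whereas $d \ast \chi$ on the
  patch grid is self-consistent.
* **L1 loss** — $\mathrm{mean}\,|\hat\chi - \chi|$.
* **gradient loss** —
  $\mathrm{mean}\sum_{a}\bigl||\nabla_a \hat\chi| - |\nabla_a \chi|\bigr|$
  with forward finite differences and replicate boundary (the difference at
  the last slice is zero), an edge-preservation term that is invariant to
  constant offsets.

The loss is evaluated in the z-scored space; since all three terms are
1-homogeneous in the discrepancy, a common rescaling does not change their
relative weighting.  Training uses Adam (initial learning rate $10^{-3}$,
batches of 8, 160 epochs at the reference scale).  The learning rate decays
by a factor 0.1 when the validation loss fails to improve by at least a
relative $10^{-4}$ for 10 consecutive epochs (both configurable; the first
epoch establishes the baseline), and the parameters with the best
validation loss are retained.  All randomness (initialization, shuffling)
derives from the configuration seed, and the compiled single-precision
engine is deterministic at a fixed thread count, so identical
configurations reproduce identical training logs.

### Classical baseline

`tkd_inversion()` implements truncated k-space division: divide by $D$
where $|D| > \tau$ and clamp the divisor to $\tau\,\mathrm{sign}(D)$ in the
ill-conditioned band (the standard sign-preserving variant; hard zeroing is
available via `mode = "zero"`).  On the high-fidelity subspace TKD is exact
by construction, which the tests verify to $10^{-8}$.

## Synthetic data

The in-vivo data this class of methods is trained on (multi-orientation
gold-standard reconstructions as labels) is emulated by a synthetic module:

* `generate_phantom()` — piecewise-constant sources (spheres, ellipsoids,
  cuboids) with susceptibilities drawn uniformly from $(-0.2, 0.2)$ ppm
  (a literature-typical brain tissue range; configurable, not a measured
  constant) inside an ellipsoidal "brain" mask with semi-axes
  $(0.8, 0.9, 0.75)$ of the half-extent — a shape that produces realistic
  patch tissue fractions for the 10 % retention rule;
* `insert_lesion()` / `simulate_hemorrhage_case()` — a sphere overwritten
  with a high susceptibility (default 1.0 ppm, hemorrhage-like) and the
  forward-simulated noisy field (default Gaussian noise of 0.005 ppm,
  small relative to tissue contrast; both configurable);
* `extract_patches()` — $64^3$ patches at 66 % overlap by default, with
  stride $\mathrm{round}(64 \times 0.34) = 22$, the final origin clipped
  flush to the boundary, and patches below 10 % tissue discarded;
* `augment_rotation()` — rotation about an axis perpendicular to $B_0$
  within $\pm 15^\circ$, trilinear interpolation, mask re-binarized at 0.5.
  For synthetic pairs the field is *re-simulated* from the rotated map
  rather than rotated itself — exact for simulation, whereas rotating a
  measured field volume is only an approximation;
* `split_phantoms()` — a seeded 5/2/5 train/validation/test split mirroring
  a subject-level split.

What the phantoms deliberately do **not** model: anatomical structure,
vessel and air-interface sources, background fields, phase unwrapping
residues, or scanner acquisition effects.  Tests passing on this data
validate the algorithmic machinery (operators, losses, training dynamics,
metrics) — they do not certify in-vivo reconstruction quality.

## Evaluation

`metric_report()` bundles the four standard reconstruction metrics, all
restricted to the brain mask (outside-mask voxels are undefined by
construction):

* **NRMSE** (%) — $100\,\|\hat\chi - \chi\|_2 / \|\chi\|_2$; the all-zero
  predictor scores exactly 100 %.
* **PSNR** (dB) — $20\log_{10}(\mathrm{peak}/\mathrm{RMSE})$ with peak =
  reference max − min within the mask, capped (default 100 dB) for
  identical inputs.
* **HFEN** (%) — relative $\ell_2$ error after a $15^3$,
  $\sigma = 1.5$ Laplacian-of-Gaussian filter (the de-facto standard
  parameters of the QSM reconstruction-challenge literature).  The kernel
  is normalized to zero sum and volumes are replicate-extended before
  filtering, so constant offsets are annihilated exactly, including at the
  volume boundary.
* **SSIM** — mean local structural similarity with an isotropic Gaussian
  window ($11^3$, $\sigma = 1.5$) and constants $K_1 = 0.01$,
  $K_2 = 0.03$.  The dynamic range defaults to the masked value range over
  *both* volumes, which keeps the measure symmetric in its arguments; a
  reference-anchored range can be passed explicitly.  SSIM values are
  implementation-sensitive (window, range handling), so cross-package
  comparisons should fix these choices.
* `roi_regression()` — ordinary least squares of per-ROI means against a
  reference (slope, intercept, $R^2$), as used for deep-gray-matter
  agreement analyses.

## Experiment harnesses

`run_threshold_sweep()` and `run_channel_ablation()` reproduce the two
standard design experiments as *procedures*: one matched model per
threshold in $\{0.1, \dots, 0.5\}$, or per input-channel subset at fixed
threshold, trained and evaluated on identical synthetic data with identical
budgets, reported as mean ± sd of the four metrics over the test phantoms.
The defaults are deliberately desk-scale; the harness arguments scale every
axis of the experiment (phantom counts, grid, patch size, network size,
epochs).  On synthetic data at matched small budgets the three-channel
input does not lose to the two-channel variants in median NRMSE over
repeated seeds — the direction the ablation is designed to probe — but
small-budget runs have substantial seed-to-seed spread, so single-seed
comparisons are not meaningful.

## Problem sizes used by the test suite

The suite favours small, seeded experiments: operator and metric properties
run on $8^3$–$32^3$ volumes; the sphere oracle on $96^3$ (padded to
$144^3$); the end-to-end learning check trains the reduced network (base 8,
depth 3) on two hundred overlapping $32^3$ patches (a seeded subsample of
the ~256 the pipeline extracts from four $64^3$ phantoms), with one
validation and one held-out test phantom, for 16 epochs — the package's
smoke budget, at which the learning signal (strictly decreasing early
training loss, learned inversion beating the all-zero predictor with
NRMSE < 100 % on the held-out phantom) is already unambiguous.  The harness checks run at miniature budgets (2-epoch
trainings) because they assert table *structure*, not quality.  The
acceptance script (`scripts/acceptance.R`) re-runs the same pipeline with a
12-epoch smoke training, which is where its reported NRMSE figures come
from.

## Known limitations

* The compiled engine is single-precision and single-threaded; it targets
  smoke-scale experiments, not GPU-scale training.
* Batch normalization statistics are computed over (space × batch); very
  small patches with tiny batches give noisy statistics.
* The rotation augmentation uses trilinear interpolation, which smears the
  sharp edges of piecewise-constant phantoms (the round-trip identity holds
  to a few percent only on smooth content).
* Oblique $B_0$ directions are supported by the kernel and forward model,
  but `augment_rotation()` rotates about the second grid axis, assuming
  $B_0$ close to the third axis.
* The mean susceptibility is unrecoverable by construction (DC convention);
  all reconstructions are zero-mean-convention maps.
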