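---
title: "Methods: dual-decoder CNN ensembles for prostate zonal segmentation"
author: "pzseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-decoder CNN ensembles for prostate zonal segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pzseg)
```

## The problem

Whole-gland and peripheral-zone (PZ) delineation on T2-weighted prostate MR
is the first step of gland volumetry, biopsy planning and radiotherapy
contouring, and manual contouring is slow and poorly reproducible. `pzseg`
implements a complete, testable pipeline for this task: a family of
dual-decoder residual encoder–decoder convolutional networks built from a
12-component hyperparameter vector, Bayesian hyperparameter optimization of
that vector, five-fold 2D–3D ensemble training with majority voting, the
geometric and intensity preprocessing around it, planar-contour
(RT-STRUCT-style) annotation handling, and the evaluation and cohort
statistics used to report results.

Because clinically annotated cohorts cannot ship with a package, `pzseg`
also provides a first-class synthetic phantom generator. Every stage of the
pipeline — training included — is exercised end-to-end on phantoms by the
test suite.

## The network family

A network is determined by a hyperparameter vector
$\lambda = (\lambda_1,\dots,\lambda_{12})$: seven architecture components
(residual blocks per path $n$, base filter count $f_0$, activation, the
three kernel sizes shared by all residual blocks, spatial-dropout
probability) and five real-time augmentation magnitudes (rotation, width
shift, height shift, zoom, horizontal flip).

The topology is a U shape with one encoder and **two decoders**: a
down-sampling path of $n$ residual blocks, each followed by $2\times 2$
in-plane max-pooling; one middle residual block; and two symmetric
up-sampling paths (`up-pz` for the peripheral zone and `up-pg` for the
whole gland), each consisting of $n$ stages of spatial dropout, nearest
upsampling, lateral concatenation with the matching encoder features, and a
residual block. A residual block is three [zero-padded convolution → batch
normalization → activation] sub-blocks plus an additive shortcut (a
1-kernel projection when the channel count changes). Filters double at each
deeper level from $f_0$ and mirror on the way up. A spatial dropout layer
precedes every residual block except the very first. The features of the
last `up-pz` block are concatenated into the gland head's input so the PZ
evidence informs the gland prediction; both heads are 1-kernel convolutions
with sigmoid outputs.

Design choices where the architecture family leaves freedom:

* **Lateral skips.** U-style encoder-to-decoder concatenation skips are on
  by default (`lateral_skips = TRUE`); the variant without them is a
  constructor switch, and the parameter accounting covers both.
* **Decoder branch point.** Both decoders branch from the middle residual
  block.
* **3D pooling acts in-plane only** ($2\times2\times1$). Clinical T2W
  stacks have few slices (the reference grid holds 23), which cannot be
  halved repeatedly; in-plane pooling preserves the slice count at every
  scale, in both 2D and 3D modes.
* **Upsampling** is nearest-neighbour followed by convolution rather than
  transposed convolution; it avoids checkerboard artefacts and keeps the
  parameter count identical to the mirrored encoder.
* **Initialization** is seeded He-uniform; leaky ReLU uses slope 0.01, ELU
  unit scale.

The training engine (forward pass, exact backpropagation through batch
normalization, pooling argmaxes and dropout masks, Adam updates) is
implemented natively in C++ so the package has no deep-learning framework
dependency; evaluation-mode inference is deterministic by construction.

## Losses and evaluation metrics

Training minimizes the combined two-structure soft Dice loss

$$L = 1-\frac{2\sum_i \hat y^{p}_i y^{p}_i}{\sum_i (\hat y^{p}_i)^2+\sum_i (y^{p}_i)^2+\varepsilon}
  \;+\; \alpha\left(1-\frac{2\sum_i \hat y^{pz}_i y^{pz}_i}{\sum_i (\hat y^{pz}_i)^2+\sum_i (y^{pz}_i)^2+\varepsilon}\right),$$

with $\alpha = 0.1$ by default and $\varepsilon = 10^{-6}$ for numerical
stability. Note the **squared** denominators: this is deliberate and
distinct from the evaluation-time Dice score
$DS = 2|y\cap\hat y|/(|y|+|\hat y|)$, which uses voxel cardinalities. The
two coincide exactly for binary predictions with $\varepsilon = 0$, and the
test suite asserts that identity. When a case ships no PZ reference the PZ
term is skipped and logged.

Boundary accuracy is the symmetric Hausdorff distance
$HD(y,\hat y)=\max(h(y,\hat y),h(\hat y,y))$ with
$h(y,\hat y)=\max_{a\in\partial y}\min_{b\in\partial\hat y}\lVert a-b\rVert$
in physical millimetres, over boundary voxels (mask voxels with a face
neighbour outside). The full maximum is used, not a percentile variant. A
distance against an empty mask is undefined and reported as missing, never
as zero.

Cohort-level domain shift is quantified between pooled voxel-intensity
histograms (100 uniform bins on $[0,1]$, background included) with three
discrepancies: KL divergence (with $10^{-12}$ smoothing of the reference),
1D Wasserstein distance on the intensity scale via the CDF-difference
integral, and the Jensen–Shannon distance (base-2 logs, bounded in
$[0,1]$). Whether pooled or per-case histograms and which bin count best
match published discrepancy tables is not derivable from the method
description, so these settings are the package's documented choice.

## Bayesian hyperparameter optimization

The search minimizes the validation loss $1-\text{Dice}$ over
$\Omega = \Omega_1\times\cdots\times\Omega_{12}$ sequentially: warm-up
random trials, then a probabilistic surrogate fitted to the trial history
$D_t=\{(\lambda_j, L_j)\}$ proposes the next $\lambda$ by maximizing an
acquisition function, the candidate is scored by *partial training* (a
truncated epoch budget), and the history is augmented. Concretely:

* surrogate: Gaussian process with a Matérn-5/2 kernel on unit-scaled
  encodings (one-hot categoricals), lengthscale and noise chosen by
  marginal likelihood;
* acquisition: expected improvement over a candidate pool — every
  not-yet-evaluated point for small finite spaces (which makes small
  discrete searches exhaustive and deduplicated), or 1000 random points
  otherwise;
* warm-up: 5 random trials by default.

The default space is blocks $\{2,3,4\}$, base filters $\{8,16,32\}$, the
three activations, kernels $\{3,5\}$, dropout $[0,0.5]$, rotation
$[0°,30°]$, shifts $[0,0.2]$, zoom $[0,0.3]$, flip on/off. The 2D and 3D
searches run independently on a shared space definition. The budget, warm-up
size, and partial-training epochs are configuration with these documented
defaults. The test suite verifies the search against exhaustive enumeration
on a 24-point space and against a matched random-search baseline on a
smooth continuous objective.

## Preprocessing

The standardization pipeline is `resample` → `standardize_shape` →
`normalize_intensity`:

1. **Resample** to $0.5\times0.5\times3$ mm with a cubic interpolating
   B-spline (the classic causal/anticausal recursive prefilter, with an
   exact mirror-boundary initialization for short axes); masks use
   nearest-neighbour and stay binary.
2. **Resize** to the $256\times256\times23$ reference grid by symmetric
   centre crop/pad — not anisotropic stretching, which would silently
   change the just-established resolution. Pad values are the image
   minimum (0 for masks); the applied offsets are recorded so predictions
   map back to the original grid.
3. **Normalize** each axial slice independently: clip to mean $\pm 3$ sd of
   the slice, then min-max rescale to $[0,1]$. The slice-wise reading
   governs both the clipping statistics and the rescaling. Constant slices
   map to zero.

The 2D member consumes the axial slices; the 3D member a centred
$128\times128\times23$ crop, with offsets recorded for paste-back. All
shapes and spacings are configurable; the scaled-down phantom study uses a
$16\times16\times8$ grid at $4\times4\times6$ mm with an $8\times8\times8$
crop.

## Contour handling

Reference annotations arrive either as voxel masks (NIfTI) or as per-slice
planar polygons in patient millimetres, the convention of DICOM RT-STRUCT
contour data. `pzseg` reads the polygon payload from a JSON/R-list
structure-set record carrying exactly that content; writing clinical DICOM
files is out of scope. Index/patient coordinate conversions use the affine
defined by origin, spacing and the two direction vectors, with the slice
direction as their cross product; only orthonormal (possibly oblique)
directions are supported.

Rasterization sets a voxel iff its centre is inside the polygon under the
even–odd rule; polygons sharing a slice combine by parity, which supports
holes. The boundary convention is half-open (centres on lower-index edges
count as inside), making rasterization deterministic and adjacent tilings
disjoint; the underlying method description does not fix this convention,
so it is the package's choice, asserted against a brute-force
centre-by-centre oracle. `masks_to_contours` traces pixel-square boundary
loops on the half-integer lattice, so no centre can fall on an edge and
re-rasterization is voxel-exact — the suite checks this cycle on 50 random
masks plus the 2% area-convergence bound on discs. Polygons are assigned to
the nearest slice; a plane farther than half the slice spacing from every
slice is an orphan-contour error.

## Ensemble formation

The cohort is split into 5 folds (deterministic, seeded); per fold 80% of
cases train and 20% validate, validation sets are pairwise disjoint and
cover the cohort. Reading the published 80/20-per-fold description as
disjoint cross-validation is this package's interpretation; independent
random splits are available by flag. Each fold trains one 2D member (3000
epochs by default) and one 3D member (2000 epochs), Adam with
$\beta_1=0.9$, $\beta_2=0.999$, $\epsilon=10^{-8}$, learning rate
$10^{-5}$, with real-time augmentation at the searched magnitudes; the
checkpoint with the smallest validation loss is kept.

At inference, each pair averages its two probability maps inside the 3D
crop; outside it the 2D probability stands alone (averaging against an
undefined 3D value would bias toward background). Each pair's fused map is
thresholded at 0.5 and the five binary masks are combined by strict
majority vote; an average-then-threshold variant is available by flag,
since the published description does not pin the order down. No
post-processing (largest-component filtering, hole filling) is applied by
default. Predictions are mapped back to the input volume's original grid
through the recorded crop offsets and nearest-neighbour resampling.

## The phantom generator

The generator emulates the cohort statistics that drive the pipeline's
behaviour, not MR physics:

* **Gland**: an ellipsoid sized to a target volume (defaults span the
  25–70 cm³ range of clinical cohorts) with mild axis anisotropy and a
  smooth band-limited radial boundary perturbation; the largest 6-connected
  component is kept. Requested volumes that cannot fit the grid raise an
  error naming the feasible maximum.
* **PZ**: the posterior outer shell of the gland — voxels in the posterior
  half with the largest normalized ellipsoid radius — sized to a target
  fraction of the gland (defaults 0.2–0.35, matching reported PZ-to-gland
  volume ratios). This yields the anatomically expected posterior crescent
  in axial slices and guarantees PZ ⊂ gland by construction. No
  quantitative PZ shape statistics are available to calibrate beyond the
  volume ranges.
* **Intensities**: Gaussian region means plus additive Gaussian noise. The
  `bimodal_heavy_tail` profile has a dark background mode, a bright tissue
  mode and a log-normal bright subpopulation producing the heavy right
  tail seen in some cohorts; `unimodal_low_contrast` compresses all
  regions below ≈0.2, emulating low-contrast cohorts. Rician noise and
  coil bias fields are not modelled.
* **Seeding**: geometry and intensity noise are seeded separately, so a
  cohort can fix geometry while varying noise; identical spec and seed is
  bit-reproducible.

What passing tests on phantoms does and does not show: phantoms share the
geometry, volume ranges, containment structure, anisotropic sampling and
intensity-distribution shifts of real cohorts, so they exercise every
pipeline contract (geometry round-trips, loss behaviour, fold bookkeeping,
fusion and voting, statistics). They lack real anatomical texture,
inter-rater ambiguity and scanner artefacts, so phantom Dice levels say
nothing quantitative about clinical performance — only that the machinery
optimizes, fuses and evaluates correctly.

## Scaled-down study sizes

The packaged experiments run a deliberately small study so the entire
pipeline trains in minutes on one CPU: 40 training and 20 held-out
phantoms on $16\times16\times8$ grids at $4\times4\times6$ mm (gland
volumes ~28 cm³), a 1-block/4-filter network pair, 5 folds, 50 epochs per
member at learning rate $2\times10^{-3}$. Under these packaged conditions
the suite asserts that every member's best validation loss beats its first
epoch, that held-out majority-vote gland Dice reaches at least 0.80, and
that the vote does not fall more than 0.02 behind its mean member;
`scripts/acceptance.R` recomputes the same quantities from scratch.

## Numerical choices and degenerate inputs

* Soft-Dice $\varepsilon = 10^{-6}$; KL smoothing $10^{-12}$; empty-vs-empty
  Dice score defined as 1; Hausdorff against an empty mask is an error.
* Constant slices normalize to zero (avoids 0/0); B-spline resampling
  reproduces constants to machine precision (partition of unity).
* Zero-area contours rasterize to nothing with a warning; empty structure
  sets parse with a warning, not an error.
* Candidate training that diverges to a non-finite loss is recorded as the
  worst loss with a warning and the search continues.
* Welch comparison of two zero-variance equal-mean samples returns $p=1$;
  an all-zero paired difference is a declared tie with $p=0.5$.
* Volume-quartile stratification is rank-based: cases sorted by reference
  gland volume (ties by case id) are split at the 25/50/75 positions. For
  distinct volumes this coincides with splitting at interpolated empirical
  percentiles, and under ties it keeps the partition exact with counts
  within one of each other.
* All stochastic components (phantoms, folds, initialization, dropout,
  augmentation, search) consume explicit integer seeds.

## Known limitations

* The RT-STRUCT dialect carries the contour payload only; binary DICOM
  parsing and clinical export are out of scope.
* Quartile confidence intervals use the normal-theory t interval; no
  multiple-comparison correction is applied, mirroring common reporting
  practice.
* The GP surrogate uses a single shared lengthscale; for the 12-component
  space this is coarse but sufficient for the packaged budgets.
* Shear (non-orthonormal) direction matrices are rejected.
* Training is CPU-bound native code: fine at phantom scale, not intended
  for full-resolution clinical training runs.
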