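---
title: "Methods: penumbra/core segmentation on non-contrast CT"
author: "strokeseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penumbra/core segmentation on non-contrast CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling and numerical choices behind
`strokeseg`: what is computed, which knobs matter, what the synthetic
phantoms do and do not emulate, and where the design was genuinely open.

## Problem and data model

Acute ischemic stroke produces an irreversibly damaged infarct core (IC,
label 2) surrounded by hypoperfused but salvageable penumbra (IP, label 1).
Both appear on non-contrast CT only as subtle hypodensity (a few HU below
normal parenchyma, the core slightly darker than the penumbra), on volumes
that are strongly anisotropic: roughly 0.38 mm in-plane and 5 mm between
slices. A volume is stored internally as a `(D, H, W)` array with `D` the
axial (thick-slice) axis plus a spacing triplet in mm; feature tensors add
channel and batch axes and are stored depth-fastest (`D × H × W × C × B`)
so that each channel is a contiguous block for the C++ kernels.

## Preprocessing (dataset fingerprint)

Preprocessing follows the fingerprint idiom: statistics are estimated once
from the training cohort and applied everywhere.

* **Crop** to the bounding box of voxels strictly above the volume minimum
  (inputs are assumed skull-stripped, so this is a brain-mask proxy). The
  crop box, original shape and spacing are recorded so predictions can be
  mapped back exactly.
* **Resample** to the per-axis median training spacing. Output shape is
  `round(shape · spacing / target)`, half away from zero, floored at one
  voxel. Images are interpolated trilinearly, labels with nearest
  neighbour. Linear (rather than spline) interpolation is used
  deliberately: it is monotone, cannot overshoot across the 5 mm slices,
  and keeps the resampler a single small kernel; at the phantom contrasts
  the difference to cubic schemes is far below the noise floor.
* **Normalise** by clipping to the 0.5th–99.5th percentile window of the
  pooled *foreground* (label > 0) voxels of the training cohort, then
  z-scoring with the pooled clipped mean/sd. Pooling over the segmentation
  target rather than all brain tissue mimics windowing the lesion; a
  degenerate window (zero variance) is rejected with an error. Fingerprint
  statistics pool training cases only.

## Architecture

`arch_config()` describes the network; the full-scale default is 7 encoder
levels with channels (32, 64, 128, 256, 320, 320, 320), the desk-scale
default (`desk_arch_config()`) 5 levels with (8, 16, 32, 64, 64). In-plane
axes are strided by 2 at every level transition; the D axis only at the
last two transitions, so a 20 × 320 × 256 patch reaches a 5 × 5 × 4
bottleneck. Per-level channel counts are a capped-doubling scheme,
configurable, since only the mechanism — not the exact counts — is fixed
by the design.

* The **input stem** is one 3×3×3 convolution + instance norm + leaky ReLU
  (slope 0.01, learned affine norm, biases everywhere).
* **MSC blocks** (every level): a 3×3×3 convolution block producing `X′`,
  a 3×3×3 depthwise convolution `U`, parallel decomposed depthwise
  branches `DWConv(1,k,k)` then `DWConv(k,1,1)` for k ∈ {5, 7, 11} with no
  norm/activation, an identity branch, and a 1×1×1 fusion convolution
  block whose output is added to `X′`. The through-plane extent of the
  `(k,1,1)` member is clipped to the largest odd value not exceeding the
  level's reference depth (a 5-slice grid cannot support an 11-slice
  kernel); the normalisation sits inside the fusion block, exactly where
  the block equations place it.
* **SE blocks** (deepest four levels): concatenate the feature map with
  its left–right mirror difference and fuse with a 1×1×1 convolution
  block, plus a residual. For mirror-symmetric activations the difference
  operand is identically zero, so asymmetry is the only signal the extra
  channels carry. The mirrored axis defaults to W (left–right) and is
  configurable.
* **Attention gates**: gating is computed at the skip's resolution — the
  decoder feature is first upsampled by a transposed convolution with
  kernel = stride (non-overlapping), then `a = σ(ψ(ReLU(W_g·g + W_x·s)))`
  with intermediate channels half the skip channels; `a ∈ (0,1)` strictly,
  so the gated skip never exceeds the skip in magnitude. The upsampled
  feature and gated skip are concatenated and fused by one 3×3×3
  convolution block per decoder level.
* **Heads**: one 1×1×1 convolution per decoder level; the deeper half
  predict 2 classes, the shallower half 3. Ties at the final argmax go to
  the lowest class index.

## Loss and supervision

Each level's loss is `α·L_Dice + β·L_CE` with α = β = 1: soft Dice with
smoothing ε = 1e-5 in numerator and denominator, computed per sample over
foreground classes only and averaged over the batch; cross-entropy as the
voxelwise mean. Ground truth is downsampled to each head's grid with
nearest neighbour (deterministic and label-preserving), merging IP and IC
at 2-class levels. The total is the weighted sum with
Res = (0.02, 0.08, 0.2, 0.1, 0.2, 0.4) deepest-first for six levels (they
sum to 1); for other depths, weights proportional to 2^i, normalised. At
3-class levels the per-region sum `L_IP + L_IC` is realised as one full
Dice loss per foreground region plus the shared 3-class cross-entropy
counted **once** — counting it per region would silently double its
weight; `ce_mode = "per_class"` provides that reading too.

Gradients for the compound loss are computed analytically (softmax chain
rule) rather than by taping the elementwise ops — one node per head keeps
the tape small.

## Training

SGD with Nesterov momentum 0.99 and weight decay 2e-5; initial learning
rate 1e-2 decayed as `lr₀·(1 − epoch/epochs)^0.9`; global gradient-norm
clipping at 12; random patches with foreground oversampling: a 1/3
fraction of the sampled patches is forced to contain a lesion voxel,
scheduled as a regular cadence over steps (whole batch slots first, the
fractional remainder as every k-th step) rather than i.i.d. coin flips, so
lesion exposure never suffers random streaks. Augmentation probabilities are rotation 0.2
(±30° about the through-plane axis only, given 5 mm slices), scaling 0.2,
mirror 0.5 per enabled axis, Gaussian noise 0.1, blur 0.2, low-resolution
simulation 0.25, gamma 0.3, contrast/brightness 0.15; elastic deformation
is implemented but defaults to probability 0, matching current practice.
Full-scale defaults are 300 epochs × 250 iterations at batch 2 with
20 × 320 × 256 patches.

**Desk scale.** All experiments shipped with the package run a single-CPU
configuration chosen once: 5 levels at ≤64 channels, 16 × 64 × 64 patches,
batch 1, 12 epochs × 50 iterations (600 optimisation steps), 30 training
and 10 held-out phantoms. One optimiser constant is rescaled at this
scale: desk momentum is 0.95 instead of 0.99. The full-scale momentum is
calibrated for ~3 million voxels per optimisation step; a desk step
carries 65 thousand, and the amplified gradient noise at 0.99 can trap a
600-step schedule in the all-background regime (the per-sample Dice term
rewards predicting nothing whenever a patch lacks lesion). The full-scale
default keeps 0.99. Large-tensor convolutions execute their GEMMs in
single precision (small tensors, all reductions and the optimiser state
stay double); this is a size-thresholded mixed-precision scheme, standard
for network training, and is why the pipeline fits in minutes on one core.

## Inference

Gaussian-weighted sliding windows: window = training patch, stride = half
the patch, final windows aligned to the far edge, per-axis σ = 1/8 of the
patch extent, peak weight 1. Accumulated probabilities are renormalised so
they remain a convex combination of window softmaxes (order-independent by
construction). Volumes smaller than the patch are symmetrically padded
with the background-normalised value and un-padded afterwards. Flip
test-time augmentation averages the 8 axis-flip predictions. Only the
full-resolution 3-class head produces the segmentation; deep heads are
training-only. No morphological post-processing. The argmax map is
restored to native geometry (nearest-neighbour resample into the recorded
crop box).

## Synthetic phantoms

The generator (`generate_phantom()`, `generate_cohort()`) emulates the
features the method actually exploits: a bilaterally symmetric head
(ellipsoid plus mirrored ventricle-like dark pair) so symmetry-difference
features are informative; a hypodense penumbra ellipsoid with a darker
core nested inside it, confined to one hemisphere (draws violating this
are rejected and resampled); slight in-plane head tilt; additive Gaussian
noise; and the cohort's voxel anisotropy (default 20 × 160 × 128 voxels at
5 × 0.4 × 0.4 mm). Default contrasts are bg 30, penumbra −3…−5, core a
further −2.5…−5 pseudo-HU below that, noise σ 1–2 — chosen to sit in the
"slight hypodensity" regime rather than an easy high-contrast one. True
volumes are analytic (4/3·π·abc), which makes volumetry exactly checkable.

What the phantoms do **not** emulate: CT physics (beam hardening, partial
volume beyond grid discretisation), skull and extra-axial structures, real
anatomical texture, irregular lesion shapes, and the DWI/FLAIR-derived
label noise of clinical ground truth. Passing the phantom study therefore
demonstrates that the pipeline is mechanically correct and can learn
subtle unilateral hypodensity at clinical anisotropy — not that clinical
accuracy figures transfer.

At the desk scale the held-out phantom study recovers the merged lesion
with mean Dice in the high 70s to mid 80s across seeds, the core and
penumbra individually in the 65–85% range, total-volume Pearson r of
0.86–0.99 and dichotomisation accuracy of 80–100%. The spread across
seeds is real: 600 optimisation steps sit near the edge of what the
3-class discrimination needs, and the cross-entropy term initially
settles at class priors, contributing late for rare classes (the Dice
term does the early lifting — the desk momentum choice above is what
keeps that phase stable).

## Numerical notes and degenerate inputs

* Instance norm uses ε = 1e-5 inside the square root; Dice uses ε = 1e-5
  in numerator and denominator, so an empty target yields a well-defined
  (≈1) Dice loss that rewards predicting nothing.
* Equal logits at argmax resolve to the lowest class index.
* Resampling maps output voxel centres to input centres
  (`x_in = (i + 0.5)·n_in/n_out − 0.5`), so a ratio of 1 is the exact
  identity for both schemes.
* Surface metrics define the boundary as foreground voxels with a
  face-adjacent background neighbour (volume edge counts as background);
  HD95 is the 95th percentile of the pooled directed distances, ASSD the
  mean of the two directed means. Empty masks flag the metrics undefined;
  cohort summaries exclude them and report the exclusion count
  (zero-filling is available as an option).
* Dichotomisation CIs: exact binomial (accuracy), large-sample (kappa),
  seeded 2000-draw bootstrap (AUC; DeLong optional). For phantom cohorts
  the 70 mL clinical cut-off is replaced by the cohort median of the true
  total volumes, which guarantees both classes are populated.

## Known limitations

* The desk-scale budget leaves seed-to-seed spread in the 3-class
  discrimination (above); full-scale schedules are two orders of magnitude
  longer.
* The transposed-convolution upsampler uses kernel = stride; overlapping
  kernels would be a drop-in replacement but add checkerboard-prone
  parameters with no benefit at these scales.
* NIfTI orientation handling assumes axial volumes with the thick axis
  third in the header (x, y, z → W, H, D); arbitrary affines are recorded
  but not reoriented.
* The brute-force surface-distance kernel is quadratic in boundary size —
  fine for head-CT lesions, slow for organ-scale masks.
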