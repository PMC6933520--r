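---
title: "Joint segmentation of glioma sub-regions and white matter hyperintensities: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint segmentation of glioma sub-regions and white matter hyperintensities: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most adults past middle age carry some burden of white matter
hyperintensities (WMH) — bright T2/FLAIR lesions from small vessel
ischemic disease and chronic infarcts.  In a subject who also has a
glioma, both processes produce abnormal T2/FLAIR signal, and a
segmentation model trained only on tumor classes has no vocabulary for
the WMH it will inevitably encounter: distal WMH tend to be absorbed
into the peritumoral-edema or necrosis classes as false positives far
from the tumor, which inflates boundary-error metrics even when overlap
scores look excellent.  `gliowmh` implements a joint 4-/5-class
volumetric segmentation pipeline that treats WMH as an explicit fifth
class next to the three glioma sub-regions, together with the evaluation
stack needed to quantify what the extra class buys.

Throughout, label volumes use the BraTS on-disk convention: background
0, necrotic core (NCR) 1, edema (ED) 2, enhancing/active tumor (AT) 4,
with WMH as code 3.  Composite evaluation regions are whole tumor
WT = NCR ∪ ED ∪ AT, tumor core TC = NCR ∪ AT, and enhancing tumor
ET = AT; WMH is never part of a tumor region.  Because the 4-class
output omits code 3, contiguous class indices and on-disk codes differ;
`label_codec()` pins that bijection in one place.

## Network and training procedure

The model is a 3D U-Net: an encoder of `levels` resolution stages (two
nodes per stage, each node a zero-padded 3×3×3 convolution with stride
1, ReLU, then batch normalization), 2×2×2 max-pooling between stages, a
mirrored decoder using 2×2×2 transposed convolutions, skip connections
concatenating each encoder output onto the matching decoder input, and
a final 1×1×1 convolution to per-class scores.  Channel width starts at
`base_filters` and doubles per stage.  The reference configuration is 4
input channels (T1, post-contrast T1, T2, FLAIR), 4 levels and 32 base
filters; the 4- and 5-class variants are identical except for the
classification head.

Training minimizes unweighted voxelwise multi-class cross-entropy with
Adam (initial learning rate 1e-4 at reference scale) under a 2nd-order
polynomial decay, `lr(e) = lr0 (1 - e/E)^2` over `E` epochs.  Weights
use Xavier-uniform initialization.  Patches of 80³ voxels (reference
scale) are sampled with centerpoints drawn 90% uniformly from lesion
voxels and 10% uniformly from the brain mask; cases without lesion
voxels fall back to brain-uniform sampling so the sampler is total.
Train-time augmentation applies a fair-coin left-right flip followed by
a constrained affine warp: per-axis rotations up to ±45°, per-axis
scaling in [0.75, 1.25], shears within ±0.1.  Images are resampled
trilinearly, labels by nearest neighbour, so no new label values can
appear.  Whole volumes are zero-padded at the high-index end of each
axis to the next patch multiple (240×240×155 → 240×240×160 for an
80-voxel patch) — padding placement is a convention this package pins;
inference is whole-volume, fully convolutional, with batch-norm running
statistics frozen.  Ensembles retrain the model independently with
derived seeds and average softmax probabilities before the argmax
(ties resolved toward the lowest class index, so outputs are
deterministic);  k-fold cross-validation is available separately via
`make_folds()`/`cross_validate()`.

The whole engine — convolutions via slab-chunked im2col + GEMM,
pooling, transposed convolutions, batch-norm, Adam — is compiled in the
package (RcppArmadillo) and is exact enough to pass a finite-difference
gradient check of the full network at 1e-4 relative tolerance.  All
randomness flows through R's RNG, so training is bit-reproducible from
a single seed on one worker.

Two choices the architecture description leaves open are pinned here as
configuration: the node order is convolution → ReLU → batch
normalization; downsampling is max-pooling and upsampling a transposed
convolution, the reference U-Net choices.  Batch size (2) and patches
per epoch (200 at reference scale) are likewise configurable defaults.
Per-channel z-scoring over the brain mask precedes both training and
inference; the brain mask itself is the union of nonzero voxels across
the four channels, which is exact for skull-stripped inputs with zero
background.

## Evaluation metrics

Overlap is the Dice coefficient `2TP/(2TP + FP + FN)` on binary region
masks.  When both masks are empty, Dice is undefined and reported as
`NA` (an option scores it 1, the convention some evaluation portals
use); empty-versus-nonempty scores 0.  Boundary error is the symmetric
95th-percentile Hausdorff distance: surfaces are mask voxels with at
least one face-adjacent (6-connected) background neighbour, grid
borders counting as background; each direction's nearest-neighbour
distances (in mm) are summarized by their 95th percentile with linear
interpolation between order statistics, and the reported value is the
maximum of the two directed percentiles.  A pooled-percentile variant
is available, and both variants are tested against a brute-force
all-pairs oracle.  The percentile-of-max convention, the surface
connectivity and the interpolation rule are all deliberate pins: they
make the metric bit-stable across runs and implementations.

Cohort analyses mirror the standard volumetric workflow: Pearson (or
Spearman) correlation between manual and predicted volumes,
Bland–Altman bias with 1.96-sd limits of agreement, prevalence counts
of cases with at least 100/1000/5000/10000 mm³ of WMH (inclusive
thresholds, matching "at least"), median Dice stratified by those same
truth-volume thresholds, correlation of Dice with (optionally log10)
lesion volume excluding zero-volume cases and reporting the exclusion
count, and a paired two-tailed t-test for comparing per-case metrics
between the 4- and 5-class arms.  For the WMH volume correlation the
cohort is restricted to cases with at least 100 mm³ of true WMH.  Even-
sized strata use the mean of the two central order statistics as the
median.  Degenerate inputs are flagged rather than silently scored:
zero-variance correlations and constant nonzero paired differences
return an undefined flag, while identical pairs return t = 0, p = 1.

## The synthetic phantom cohort

No public imaging data ships with the package; everything is exercised
on a seeded synthetic mpMRI phantom that reproduces the *geometry and
contrast relationships* the task depends on, at configurable grid size
(64³ default for testing):

* an ellipsoidal brain with two ventricles (CSF contrast: dark T1/FLAIR,
  bright T2), intensities exactly zero outside the brain;
* one tumor complex built from three concentric, randomly oriented,
  radius-jittered ellipsoids — necrotic core strictly inside the
  enhancing rim strictly inside the edema envelope — lateralized into
  one hemisphere;
* zero or more WMH blobs (perturbed ellipsoids) whose centers are drawn
  uniformly from the voxels that keep the whole blob inside the brain
  and at a configurable clearance from the edema surface, with an 80%
  preference for the hemisphere contralateral to the tumor;
* class-mean intensities per channel plus additive Gaussian noise
  (sd 5 by default, in arbitrary units roughly 1/20 of the dynamic
  range).  The profile is chosen so that AT is the brightest class on
  post-contrast T1, NCR dark there, ED and WMH identically hyperintense
  on T2 and FLAIR, and WMH iso-intense to normal brain on post-contrast
  T1 while ED sits below it — so the ED/WMH distinction requires the
  post-contrast channel and/or spatial context, which is exactly the
  discrimination the fifth class exists to learn.

Tumor radii are fixed per spec (with per-axis jitter), so tumor volumes
are roughly constant across a cohort by default; `tumor_scale_range`
optionally draws a per-case global tumor scale to emulate the large
inter-subject volume spread of clinical cohorts, which matters whenever
volume-agreement statistics are the object of study.  Per-case target
WMH loads are spread evenly across a configurable range
(0–12000 mm³ by default) so that all four prevalence strata are
populated in a 20-case cohort; blob radii lean toward the upper half of
their range while a case is far from its volume target, backing off
when a radius proves unplaceable for the sampled anatomy.  Realized
per-class volumes are stored with each case and tested against
independent recounts.

What the phantom does *not* model: bias fields, partial-volume effects,
anisotropic voxels, registration error, anatomy beyond one brain-shaped
ellipsoid, and lesion textures.  Passing the scaled-down studies
therefore demonstrates that the pipeline (sampling, augmentation,
optimization, inference, metrics, statistics) is correct and learnable
end-to-end — not that the network would reach any particular accuracy
on clinical data.

## Scaled-down study sizes

The shipped tests and `scripts/acceptance.R` run two studies sized for
a single CPU; the sizes are package choices, stated here once:

* **Segmentation quality** — 20 cases at 64³, 5-class model with 2
  levels and 8 base filters, 32³ patches, 30 epochs × 16 patches,
  batch 2, Adam at 3e-3 (the reference 1e-4 is far too slow for a
  30-epoch budget), flips plus ±15° affine warps; 15 train / 5 held
  out.  The shipped check asserts held-out whole-tumor Dice ≥ 0.7,
  which this budget clears comfortably.
* **4- vs 5-class comparison** — 24 cases at 48³ with the tumor radii
  scaled to that grid (core 3 mm, rim 2 mm, edema margin 3 mm), every
  case with ≥ 2 distal WMH blobs (500–4000 mm³ total), 24³ patches,
  20 epochs × 12 patches per arm, 18 train / 6 held out, identical
  budgets in both arms; the 4-class arm trains on labels with WMH
  remapped to background, exactly how a tumor-only annotation would
  look.  The shipped check asserts the direction — the 5-class arm's
  median held-out whole-tumor HD95 does not exceed the 4-class arm's —
  by majority over three fixed seeds, because at this scale individual
  seeds can tie (both arms segment cleanly) or flip on training noise.

## Known limitations

* The compiled engine is CPU-only, double precision, single threaded
  apart from BLAS; reference-scale training (600 epochs, 285 cases,
  80³ patches, 32 base filters) is expressible but not practical
  without substantial hardware.
* Batch normalization uses per-batch statistics over all voxels of the
  batch; very small batches at tiny patch sizes still normalize over
  thousands of voxels, so this is benign in practice.
* The phantom's lesion boundaries are smooth ellipsoid unions; HD95
  values on phantoms are therefore optimistic relative to the ragged
  boundaries of real lesions.
* Dice/HD95 conventions for empty masks and percentile interpolation
  vary across published evaluation tools; this package pins one set of
  conventions (documented above) and exposes the common alternatives as
  options.
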