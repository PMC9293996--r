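---
title: "Anisotropic U-Net liver lesion segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anisotropic U-Net liver lesion segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aunetseg)
```

## The problem

In the late hepatocellular phase of dynamic contrast-enhanced liver MRI
(about 15 minutes after injection of a hepatocyte-specific contrast agent),
healthy liver parenchyma is stained bright while malignant tissue remains
unstained and appears hypointense. `aunetseg` implements a complete pipeline
for automatic segmentation of such liver lesions: preprocessing, an
anisotropic 3D U-Net trained with a liver-masked Dice loss, multi-model
training by successive halving, morphological false-positive suppression at
the liver border, and a multi-rater evaluation framework. Because clinical
late-phase MRI cannot be redistributed, the package ships a synthetic
phantom generator so that every stage is exercised end to end on data with
known ground truth.

## Data model and conventions

A `volume` is a 3D array with per-axis voxel spacing and world origin in mm;
arrays are indexed `(x, y, z)` with the first two axes in-plane and the
third across slices. This matches the anisotropic acquisition the method is
designed for: in-plane resolutions of 0.74–1.76 mm against slice thicknesses
of 2–5 mm. Masks (`mask_volume`) are binary volumes on the same grid, stored
as unsigned 8-bit integers in NIfTI.

Throughout the package, **a lesion is a 6-connected component** (face
connectivity) of a binary mask. This is one global convention; the stricter
of the standard choices, applied consistently in the phantom generator, in
lesion labeling, and in detection scoring.

## Preprocessing

Volumes are resampled in-plane to 1 mm (linear interpolation for images,
nearest neighbor for masks); slices are never resampled, so the working
voxel size is 1×1×z mm with the original slice spacing z. The resampled
grid keeps the world origin, and the new in-plane shape is
`round(shape * spacing / 1mm)` (round half up).

Gray values are normalized by linearly mapping the 2nd and 98th percentiles
of the voxels inside the liver mask to 0 and 1 — **without clipping**, so
lesions can map below 0 and bright vessels above 1. Percentiles use linear
interpolation between order statistics (`stats::quantile` type 7); the
definition is configurable because different conventions shift the mapped
values slightly. Percentiles are fit on the resampled grid (order
documented here and configurable through the pipeline; fitting before or
after an in-plane resampling changes them only marginally because the
interpolation preserves the intensity distribution of a smooth region).
Normalization parameters are fit per case and applied to the full volume,
not only the liver, because the network sees patches with non-liver
context.

## The anisotropic U-Net

The network is a five-level U-Net in which all convolutions are **valid**
(unpadded): every convolution shrinks the feature map, the output patch is
smaller than the input patch, and tiled inference is exactly
shift-consistent — predicting a voxel from any tile that contains it gives
the same value. Each block has two 3×3×1 convolutions; each convolutional
unit is followed by batch normalization and ReLU (the final 1×1×1 output
convolution, with a sigmoid, is the exception). Downsampling is 2×2×1 max
pooling, upsampling a 2×2×1 transposed convolution, and skip connections
center-crop the encoder feature maps before concatenation.

Through-plane context enters only in the three lowest-resolution levels via
unpadded 1×1×3 convolutions. The published patch geometry — input
236×236×72, output 52×52×32, symmetric margin 92×92×20 — fixes exactly how
many such convolutions the path through the network may contain: the margin
of 20 slices on each side means 40 slices are consumed, i.e. 20 unpadded
1×1×3 convolutions along the encoder–bottom–decoder path. Five blocks lie
on that path at the three lowest levels (encoder 3, encoder 4, bottom,
decoder 4, decoder 3), so each contains four 1×1×3 convolutions: **two
after each of its two in-plane convolutions** (`z_convs_per_conv = 2`).
`compute_patch_geometry()` verifies the resulting layer list symbolically;
the default configuration reproduces 52×52×32 and 92×92×20 exactly, and the
margin is independent of the admissible input extent, as it must be for a
purely convolutional network.

Decisions the architecture description leaves open, and the defaults chosen:

* **Feature counts**: 32 at the first level, doubling per level, capped at
  512; configurable, since the geometry (the testable part) does not depend
  on widths.
* **1×1×3 placement**: appended after the in-plane convolutions
  ("followed by"), not replacing them.
* **Dropout**: rate 0.1 after the deepest encoder block only.
* **Final activation**: single-channel sigmoid, matching the binary
  lesion-vs-background task and the downstream 0.5 threshold.
* **Weight initialization**: Glorot uniform (the Keras default named for
  the original training setup), zero biases, unit batch-norm scale.
* **Tiled inference** mirrors the volume at its borders where an input
  window exceeds it; mirroring avoids artificial intensity edges. The
  liver bounding box is tiled with non-overlapping output windows, and the
  result is independent of the traversal order.

The network, its forward/backward passes and the Adam optimizer are
implemented in-package (C++ kernels via Rcpp/RcppArmadillo with an R
orchestration layer); gradient correctness is established against central
finite differences in the test suite.

## Training

* **Loss**: smoothed Dice loss `1 − (2Σwpt + s)/(Σwp + Σwt + s)` with
  `s = 1`, computed **within a dilated liver mask** (weight `w`). The
  dilation is a per-slice disk of radius 5 voxels plus one slice in z
  (configurable; the description gives no radius). A small dilation keeps
  the liver border context that post-processing later targets. The loss is
  computed per batch sample and averaged.
* **Sampling**: 90 % of patches must contain at least one tumor voxel and
  the rest at least one liver voxel. The mix is enforced as a deterministic
  9:1 cycle over served patches (the description does not say whether the
  split holds per batch or in expectation; a cycle gives both at scale).
  "Contains" refers to the output (loss-contributing) region: a lesion that
  only appears in the input margin contributes nothing to the loss.
  Tumor-biased requests on lesion-free cases fall back to liver-biased
  sampling with a logged message.
* **Optimizer**: Adam, learning rate 1e-4 (unspecified in the original
  description; standard default), batch size 2.
* **Validation**: every 500 iterations, full-volume predictions on the
  validation cases are binarized at 0.5 inside the (undilated) liver mask,
  and the mean Jaccard coefficient over cases is recorded. The parameter
  state with the highest validation Jaccard becomes the final model; ties
  resolve to the earliest iteration.

## Multi-model training

Successive halving with a fixed bracket: 16 runs with seeds
`base_seed + 0..15` (identical initialization *distributions*, different
draws), halved at 5k, 10k, 20k and 40k iterations by the validation Jaccard
measured **at the shared milestone** (equal budget, not each run's
historical best), survivor trained to 80k. The default bracket totals
240,000 iterations, 3× the single training. No hyper-parameters are
searched — the bracket only explores the initialization lottery, which is
why the full Hyperband bandit over brackets is not used. A run's optimizer
state and RNG stream survive across stages (resume-from-checkpoint), so a
schedule `(1, N)` is identical to a single training of N iterations. Runs
execute sequentially; a worker count is accepted for interface
compatibility and can only affect wall time, never results.

## Post-processing

The raw probability output is restricted to the liver mask and thresholded
at 0.5 (strict `>`, so a voxel exactly at the threshold is background — the
description does not fix the boundary case, and a fixed convention keeps
the threshold reproducible). Thin false positives at the liver border are
then removed: the liver mask is eroded with a 7×7 kernel, the border region
is the original minus the eroded mask, and the tumor voxels inside the
border region are filtered with a 3×3 opening. Kernels are **per-slice
squares** (z extent 1): the kernels are written with two dimensions in an
otherwise three-dimensional method description, and with 2–5 mm slices 2D
morphology is the natural reading. Interior tumor voxels are never touched;
the cleanup never adds voxels and is idempotent.

## Evaluation

* **Segmentation**: Dice score of the prediction against each rater and
  its mean, the mean pairwise inter-rater Dice, and the uncertainty-aware
  score `phi = max(1 − alpha * eps_hat / eps_bar, 0)` with
  `eps_hat = 1 − mean(D(pred, Ri))`, `eps_bar = 1 − mean(D(Ri, Rj))` and
  `alpha = 0.1`. `phi >= 0.9` marks performance as good as the raters given
  their disagreement; `phi` is undefined (NA, with a warning) when the
  raters agree perfectly. Per-case `phi` values are averaged for summaries
  (consistent with a per-case score plot; recomputing a single score from
  summary Dice means gives a slightly different number, as the test suite's
  hand-evaluated example shows).
* **Detection**: lesions of reference and prediction are clustered into
  N:M correspondences on the bipartite overlap graph. The initial
  correspondences are the connected components of that graph; a greedy
  refinement removes, one edge at a time, the edge whose removal most
  increases the mean per-correspondence Dice, until no removal improves it.
  The per-correspondence Dice is computed on the union of the member
  components' voxels — the only reading under which it is well-defined for
  N:M groups. In the objective, components detached from all counterparts
  count as zero-Dice singleton groups; otherwise the mean could be gamed by
  discarding genuine low-overlap pairs, and a single overlapping pair with
  Dice below 0.2 must survive as a correspondence (it is then counted as a
  false positive *and* a false negative downstream, not silently dropped).
  On small instances (≤ 8 components) the greedy result equals the
  brute-force optimum over all edge subsets; this equivalence is the
  testable contract since the reference clustering algorithm is not fully
  specified. Correspondences with Dice > 0.2 are true positives;
  sub-threshold correspondences add one FP and one FN; unmatched reference
  and predicted components add FNs and FPs respectively. Degenerate
  conventions (documented, not given in the description): no predicted
  lesions → precision 1; no reference lesions → recall 1. FPC (false
  positives per case) is summarized by the median across cases.
* **Statistics**: two-sided Wilcoxon signed-rank tests (exact distribution
  below 25 pairs, normal approximation with continuity correction
  otherwise; all-zero differences give p = 1 by convention), with
  Benjamini–Hochberg step-up at FDR 0.05 across each comparison family.

## The phantom generator

The generator emulates what the method needs from late-phase liver MRI:

* an anisotropic grid — default 1.2×1.2×3.0 mm, the middle of the published
  acquisition ranges (in-plane 0.74–1.76 mm, slices 2–5 mm);
* a bright liver (an ellipsoid with a low-frequency random boundary
  perturbation) on a darker background;
* hypointense ellipsoidal lesions (default 3 per case, radii 4–12 mm,
  intensity 0.45× parenchyma), placed fully inside the liver by rejection
  sampling with a 1000-retry cap and a one-voxel separation gap so each is
  its own 6-connected component;
* additive Gaussian noise (default SD 20 against a parenchyma mean of 400,
  i.e. 5 %);
* a per-case global intensity scale (0.7–1.3) and offset (±60) emulating
  the non-standardized gray-value scale of MRI;
* simulated raters: per-lesion random dilation or erosion up to a magnitude
  in mm (default 2 mm, converted to per-axis voxel radii so anisotropic
  grids perturb plausibly), plus random dropping of small lesions
  (equivalent radius < 5 mm) with small probability — mimicking the
  observation that raters disagree most about small lesions.

What the phantoms deliberately do **not** contain: MRI physics (bias
fields, motion, coil profiles), vessel trees, multi-phase dynamics, or the
appearance diversity of real tumors. Passing the phantom suites therefore
demonstrates that the pipeline's machinery is correct (geometry, losses,
selection, morphology, scoring) and that the network can learn a
contrast-based segmentation task end to end — not that the default
configuration reaches clinical accuracy on patient data.

## Desk-scale problem sizes

The test suite trains networks at two scales, chosen so the whole suite
runs on a single CPU in minutes:

* a **tiny configuration** (3 levels, width 2, no 1×1×3 convolutions,
  44×44×8 patches) for unit-level properties of the training loop and the
  successive-halving logic;
* a **smoke configuration** with the full default 5-level anisotropic
  geometry (margin 92×92×20) but width 2, trained for 300 iterations with
  batch size 1, learning rate 3e-3 and 204×204×44 patches, validated every
  50 iterations. Inference uses 236×236×72 tiles. The patch extent matters:
  the smallest admissible input (188×188×44) yields a 4×4×4 output region —
  only 64 loss-contributing voxels — and the resulting gradient signal is
  too sparse for a 300-iteration run to learn reliably; one step up in-plane
  gives a 20×20×4 output (25× the signal) for ~18 % more compute, and the
  task then trains robustly across seeds. The learning rate is raised
  relative to the 1e-4 production default because a 300-iteration run at
  width 2 sits in a very different optimization regime than an
  80k-iteration run at width 32.

## Numerical choices

* Dice-loss smoothing constant `s = 1` (documented; configurable).
* Batch-norm epsilon 1e-5, running-statistics momentum 0.9; inference uses
  running statistics, which makes tiled prediction deterministic.
* The greedy matcher breaks ties toward the first (lowest-index) edge, and
  survivor selection toward the lower run id, making both fully
  deterministic.
* All randomness flows through explicit seeds; generators snapshot and
  restore the caller's RNG state, and training states carry their RNG so
  interrupted/resumed runs reproduce uninterrupted ones exactly.

## Known limitations

* No DICOM ingestion, oblique orientations, or 4D series — NIfTI with
  axis-aligned grids only.
* The network trains on CPU in double precision; it is sized for method
  verification, not for training clinical-scale models (no GPU, no mixed
  precision, no ensembling).
* Surface-distance metrics and qualitative expert-rating ingestion are out
  of scope; evaluation is Dice-based.
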