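---
title: "Pseudo-PET-guided lung tumor segmentation: model, training scheme and design notes"
author: "cunet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-PET-guided lung tumor segmentation: model, training scheme and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

PET/CT is the reference standard for delineating non-small-cell lung
tumors: CT contributes spatial resolution, PET contributes metabolic
contrast that makes the tumor stand out from surrounding tissue. PET,
however, is expensive and adds radiation dose, so most screening and
follow-up studies are CT-only. `cunet` implements a segmentation model
that *learns* the PET contrast from CT: a first U-Net synthesizes a
pseudo-PET image from the CT slice, and a second U-Net segments the tumor
from the CT slice with the first network's decoder features injected into
its encoder. At inference time no PET image is needed.

A second practical obstacle is that supervision is split across cohorts:
studies with acquired PET usually lack expert tumor masks, and
mask-annotated studies usually lack PET. The trainer therefore works
semi-supervised with two disjoint pools:

* **Data A** — (CT, PET) pairs, no masks: they supervise pseudo-PET
  synthesis through a mean-squared-error term **H**.
* **Data B** — (CT, mask) pairs, no PET: they supervise segmentation
  through a focal + dice term **F**, and additionally a consistency term
  **C** that compares the student's pseudo-PET on the CT slice with a
  teacher network's pseudo-PET on a randomly quarter-turn-rotated view of
  the same slice (rotated back before comparison).

The total per-step objective is `L = w·C + H + F`, with `w` following a
decaying ramp. One published variant of this objective swaps which data
pool the C and H terms attach to; the accompanying training-flow
description and figure caption are unambiguous (H needs acquired PET,
hence Data A; C and F need neither PET nor both, hence Data B), and this
package follows that reading.

The teacher is never optimized: after every student step its weights are
updated as an exponential moving average (EMA),
`teacher <- alpha * teacher + (1 - alpha) * student`, with
`alpha = min(1 - 1/(step + 1), 0.99)` so the teacher tracks the student
tightly at the start and becomes a slow average once `step >= 99`
(`emaSchedule()`). The consistency weight is
`w = 0.1 * exp(-5 * (1 - T)^2)` with `T = 1 - step/80` clamped to [0, 1]
(`consistencyWeight()`). Two interpretation choices are deliberate here:
the EMA `step` is the global optimizer iteration (the classic
per-iteration mean-teacher form), while the ramp `step` is the epoch
index, so the ramp spans 80 epochs; and `T` is clamped so `w` never ramps
back up after the 80th epoch.

# The network

Both U-Nets share one blueprint: `depth` resolution levels (default 5),
channel width doubling per level from `baseWidth` (default 48, i.e.
48/96/192/384/768), and per level two 3×3 padded convolutions, each
followed by instance normalization (with learnable scale and shift) and a
LeakyReLU. Downsampling is 2×2 max pooling with stride 2 — the source
description of the pooling stride is internally inconsistent (a stride-1
2×2 pooling cannot halve the resolution that the same description
requires), so the standard resolution-halving pooling is used. Decoding
uses a 2×2-kernel stride-2 transposed convolution followed by
concatenation with the same-level encoder skip and two further
convolution blocks; a nearest-neighbor + 2×2-convolution decoder is
available behind `upsample = "nearest"` for ablation. The PET head is a
linear 1×1 convolution (trained against PET intensities normalized to
[0, 1]); the segmentation head is a 1×1 convolution + sigmoid.

The two networks are *connected* in two ways:

1. the second U-Net's input is the channel concatenation of the CT slice
   and the first U-Net's pseudo-PET output, and
2. at every encoder level `k < depth`, the second U-Net concatenates the
   first U-Net's decoder feature of the same resolution before the
   level's first convolution.

Choice (1) is one of several plausible wirings (raw CT only, pseudo-PET
only, or both); feeding both makes the PET guidance explicit at the input
as well as via the cross skips and is the default here. At the published
configuration (base width 48, depth 5, one input channel) this dual
network holds 36,692,882 trainable scalars (`countTrainableParameters()`),
matching the published ~36.6M count to 0.24% — the exact published layer
widths are not stated, so the count anchor is what fixes the channel
plan. Convolution biases that feed instance normalization have exactly
zero gradient (the normalization subtracts the per-channel mean); they
are nevertheless standard layer parameters and are included in the count.

All network computation — forward pass, hand-derived backpropagation
through the cross-connected topology, and Adam — is implemented natively
(R + RcppArmadillo, im2col + BLAS GEMM). The backward pass is verified
against central finite differences in the test suite.

# Training procedure

`trainConnectedUNet()` flattens studies into 2D axial slices and runs,
per step: a first-U-Net pass on a Data A batch (term H), a connected pass
on a Data B batch (terms F and C, the teacher seeing a random rotated
view), one Adam step on `w·C + H + F`, and the EMA teacher update. The
learning rate follows a cosine from 1e-4 to 1e-5 across epochs; there is
no early stopping — the checkpoint with the best epoch-end validation
Dice (study-wise mean) is returned. Augmentation applies one joint
quarter-turn rotation, optional horizontal flip and random crop to every
grid of a sample; quarter-turns and integer crops involve no resampling,
so masks stay exactly binary.

Two initialization details matter for small-step-count runs. Weights use
He-style normal draws. The segmentation head bias starts at the
foreground-prior log-odds `qlogis(0.01)` — the convention introduced
together with the focal loss for rare-foreground detection — so the
network begins confidently negative on background rather than spending
its first optimizer steps suppressing half-on predictions everywhere.

**Batch composition.** Each step draws one batch from A and one from B,
with a common `batchSize` (default 8, matching the published setup, where
it was a hardware-capacity choice). The desk-scale experiments in this
package use `batchSize = 2`: with only ~200 training slices, a batch of 8
yields ~13 optimizer steps per epoch, too few for the fixed 1e-4 Adam
rate to fit anything; batch 2 gives ~1000 steps over 20 epochs while
leaving the published learning-rate schedule untouched.

# Tumor-area detection

Whole-slice predictions occasionally contain false-positive blobs far
from the tumor. `refineVolume()` implements a three-stage spatial
refinement:

1. **Rotation expansion.** Every CT slice is followed by its 90°, 180°
   and 270° rotations (`expandWithRotations()`), each predicted
   separately and mapped back to the source frame. Quadruples from
   rotated slices are un-rotated before clustering — without this, the
   2-means step would mix four coordinate frames; a literal
   no-unrotation variant would cluster rotated and unrotated tumor
   locations against each other, so the un-rotated reading is used.
2. **Quadruple extraction.** Among tumor-positive slices the longest
   contiguous run is taken (single-tumor assumption), its middle slice
   is the anchor, and up to 10 slices on each side — at most 21 in total
   (`selectTsiWindow()`) — contribute one quadruple each: the pair of
   positive pixels at maximal Euclidean distance,
   `(x_l, y_l, x_r, y_r)`, 0-based, x = column (`farthestPair()`; ties
   broken by the lexicographically smallest quadruple; large masks use
   the convex hull, since a point set's diameter is attained at hull
   vertices).
3. **Region masking and re-prediction.** The quadruples are clustered by
   standard 2-means (10 restarts, 300-iteration cap, fixed seed). The
   larger cluster — ties broken by lower within-cluster variance, then
   lower label — is averaged into two points P0 and P0', whose bounding
   rectangle, expanded by `lam` pixels per side (default 50 on the
   288-pixel reference grid) and clipped to the image, becomes the
   region mask U. The CT is multiplied by U (pixels outside set to 0;
   the fill value is configurable) and re-predicted; the returned mask
   is additionally intersected with U so the "nothing outside the
   region" contract holds even where the network's response to a zeroed
   background crosses the threshold.

If no slice contains a positive pixel the pipeline stops with an
explicit "no tumor detected" error. With fewer than two distinct
quadruples the clustering degenerates to a single cluster covering
everything.

# The phantom generator

`generatePhantom()` emulates the statistical structure the method relies
on, not anatomy: an elliptical body disc (intensity 0.5) containing two
dark lung fields (0.12) on a 0.02 background; one ellipsoidal tumor
(in-plane radius drawn from `tumorRadiusRange`, coherent across slices)
at lung + 0.45 intensity; a PET channel that is a Gaussian-blurred
(sigma 2 px) tumor indicator scaled to a hot-spot-to-background ratio of
`petContrast` (default 6 over a 0.1 background); additive Gaussian noise
(sd 0.02); and, with probability 0.2, a distractor blob in the opposite
lung. The distractor has *exactly* the tumor's CT intensity and a short
axial run, and never appears in the PET or the mask: it exists to create
false positives that cannot be resolved by intensity, only by the
spatial clustering of the area detector. Defaults are a 288×288 grid
with 48 slices (so the 21-slice window logic is exercised); the test
suite scales these down as noted below.

`makeABSplit()` reproduces the supervision structure: studies are
shuffled and divided into train/validation/test by `fractions` (defaults
0.8/0.1/0.1, which maps 126 studies to 100/13/13); training studies are
split between Data A (keeping CT + PET only) and Data B (keeping CT +
mask only).

What passing phantom tests does **not** show: phantoms are
piecewise-constant with well-separated intensities, a single tumor, and
a PET channel perfectly co-registered and deterministic given the mask.
Real CT has textured parenchyma, attachment of tumors to mediastinum and
chest wall, multi-focal disease and registration error, so phantom Dice
levels say nothing about clinical accuracy — they verify that the
optimization, guidance and refinement *mechanisms* work end to end.

# Preprocessing and metrics

`resampleToReference()` brings each slice to 1 mm spacing on a 512×512
grid, preserving physical extent (bilinear for intensities,
nearest-neighbor for masks, zero-padding or center-cropping the border);
already-conformant volumes pass through unchanged, making the operation
idempotent. `centerCrop()` takes the central 288×288 window and records
the offset in the volume origin so `unCrop()` can map predictions back.

`diceCoefficient()`, `iou()` and `hd95()` are the evaluation metrics.
HD95 is the 95th percentile (linear-interpolation quantile) of pooled
symmetric surface distances in mm, with surfaces defined by
face-adjacency (array borders count as background). Edge cases follow
fixed conventions: two empty masks score DSC = IoU = 1 and HD95 = 0;
exactly one empty mask scores DSC = IoU = 0 and an *undefined* HD95,
reported as the image diagonal in mm and flagged, so aggregate tables
stay finite. Aggregates report mean ± population SD. Evaluation defaults
to the uncropped reference grid.

# Numerical choices and degenerate inputs

* Instance-norm epsilon 1e-5 inside the square root; population variance.
* Focal loss: gamma 2, no class weighting, probabilities clipped at 1e-7.
* Dice loss smoothing 1e-6 in numerator and denominator.
* Mask binarization threshold 0.5 (both for prediction volumes and for
  resampled masks).
* Odd-sized or non-`2^(depth-1)`-divisible inputs are rejected with a
  shape error rather than silently padded; the CLI operates on generated
  grids that are already conformant.
* Quadruple tie-breaks, k-means seeding and restart counts are fixed, so
  the whole refinement pipeline is reproducible given (checkpoint, seed).
* Checkpoints are RDS containers with a plain-JSON sidecar of the model
  configuration, so a checkpoint is self-describing.

# Problem sizes used by the tests

The test suite trains two corpora, chosen as the smallest sizes at which
the mechanisms are visible: (a) 25 studies of eight 64×64 slices (200
training slices, split 10 A / 10 B / 2 validation / 3 test), base width
8, 20 epochs, batch 2 — reaching held-out Dice well above 0.6; and (b)
an ablation corpus of 14 studies of four 48×48 slices with only three
mask-labeled studies (the label-scarce regime the semi-supervised design
targets), trained at depth 4 for 10 epochs over three seeds with and
without the PET branch. The ablation is directional: the median held-out
Dice with PET guidance must be at least the CT-only median, mirroring
the guidance-helps conclusion at desk scale.

# Known limitations

* Single-tumor assumption throughout the area detector; multi-focal
  disease would need per-component windows and clustering.
* 2D slice-wise modeling; no 3D convolutions or inter-slice context
  beyond the window logic.
* The re-prediction stage sees a masked CT whose background is zeroed —
  a distribution the network never trained on; with instance
  normalization this can degrade within-region probabilities even as it
  removes all outside-region positives.
* DICOM series are not read directly; convert to NIfTI first.
* CPU-only: the native implementation is sized for desk-scale phantom
  experiments, not for full-resolution clinical training runs.
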