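---
title: "Methods: two-stage volumetric skull completion and implant extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage volumetric skull completion and implant extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cranioplasty restores a skull opening left by trauma or surgery with a
custom-shaped implant. Designing that implant from a patient's CT scan is the
slow, expert-driven step: the defective skull is a binary voxel model (1 =
bone), and the implant is, geometrically, the difference between a plausible
*completed* skull and the defective one. `craniofill` implements a two-stage
convolutional system for that completion task, together with everything
needed to exercise it end to end at desk scale: synthetic skull phantoms,
defect simulation, training, evaluation metrics, and implant post-processing.

The two stages split the work by resolution:

1. a **3-D completion network** inpaints the defective skull on a
   down-sampled grid (reference 128 x 128 x 96, 4x coarser than the native
   CT grid), where the global shape context fits into a small receptive
   field;
2. a **resolution-enhancement network** maps the completed low-resolution
   model, together with the original high-resolution defective model,
   back to the native grid (reference 512 x 512 x 384).

The implant is then `completed AND NOT scale(defective, 1.02)` — a Boolean
subtraction after a 2% uniform enlargement of the defective model that buys
fitting tolerance and suppresses thin mismatch noise outside the defect —
followed by morphological opening and connected-component filtering.

## Normalization

CT intensities are windowed to bone with an inclusive Hounsfield interval,
default [1200, 1817]; acquisition conditions vary between scanners, so the
window is a per-volume parameter, not a constant. Volumes are resampled
along the craniocaudal axis (Lanczos, order 3, edge-clamped, constants
preserved exactly) to a common slice count, and bone below the Frankfort
horizontal plane is removed. The plane is supplied as a per-volume z index:
automatic landmark detection is out of scope, and the index is the only
anatomical annotation the pipeline needs.

## Network architectures

Both networks use only 3 x 3 x 3 convolutions (stride 1, zero padding),
2 x 2 x 2 max pooling, nearest-neighbour up-sampling followed by a
convolution, ReLU activations, summation skip connections (never
concatenation), no batch normalization, and a sigmoid output head.
Predictions are thresholded at 0.45 (inclusive).

**Completion network** (10 published layers, 8,269 trainable parameters):
encoder conv(1→8), then three conv+pool stages with 8, 4, 4 filters; a
bottleneck of two dilation-2 convolutions (4 filters each, residual sums);
a decoder of three up-sampling convolutions (4, 8, 8 filters) each summed
with the same-resolution pre-pool encoder map; a final sigmoid conv(8→1)
whose output is **added to the network input** (residual input addition).
Because the encoder map at half resolution has 4 channels while the
matching decoder map has 8, that skip carries a declared 3 x 3 x 3
projection conv(4→8).

The projection is the one wiring decision the published layer table leaves
open: a literal per-row parameter sum gives 7,397, exactly one conv(4→8)
(872 parameters) short of the published 8,269. Treating the published total
as the binding constraint, an exhaustive enumeration over in-channel
assignments shows the pre-pool skip taps plus the 4→8 skip projection is
the unique faithful U-Net wiring reaching it, so that is what
`build_completion_network()` builds.

**Enhancement network** (14 published layers, 11,741 trainable parameters):
the same encoder + dilated bottleneck applied to the low-resolution
completed model; a decoder of five up-sampling stages (4, 8, 8, 8, 8
channels) carrying the result to the 4x grid, with the same pre-pool skip
sums and 4→8 skip projection as the completion network; a high-resolution
branch through which the defective model enters, is convolved (8 filters)
and max-pooled, then merged by summation with the decoder at half the
native resolution; and a sigmoid conv(8→1) head, kept in [0, 1] (no
residual addition). Its bottleneck branch for the high-resolution input has
no dilated convolutions.

Two further wiring decisions were forced by the published total. The same
enumeration shows **no** wiring in which the high-resolution input enters
through its own 1-channel convolution can reach 11,741 (a parity argument:
every 3 x 3 x 3 conv with bias contributes 27·c_in·c_out + c_out
parameters, and the achievable residues modulo 27 exclude it). The unique
consistent solution makes the second input enter parameter-free — here by
broadcasting the 1-channel volume across the branch's 8 channels before its
conv+pool stage — and leaves the final up-sampling stage as pure
nearest-neighbour interpolation. Both choices are visible in
`summary(build_enhancement_network())`, and
`count_trainable_parameters()` reports whatever the spec actually contains,
so any alternative wiring a user declares is counted honestly.

Both builders are fully convolutional: any input dims divisible by 8 are
accepted (the enhancement network additionally requires the 4x dim ratio),
and the parameter count is invariant to the dims.

## Training

Supervised training minimizes mean voxel binary cross-entropy (predictions
clipped to [1e-7, 1 - 1e-7]) with Adadelta (rho 0.95, eps 1e-6, lr 1 — the
canonical settings; Adadelta adapts its own effective step sizes).
Mini-batches average gradients (reference batch sizes: 10 for completion, 4
for enhancement); the training order is reshuffled every epoch; and the
parameters kept are those with the best validation loss, ties resolved to
the earliest epoch. Everything is reproducible from a single seed, which
drives the train/validation split, the shuffles, and the Glorot-uniform
weight initialization. Biases start at zero except the sigmoid head's,
which starts at −2 — about the logit of the bone-occupancy prior — so the
initial probability map reflects how sparse bone is instead of sitting at
0.5, which the 0.45 operating threshold would read as "all bone"; this is
the usual initialization for heavily imbalanced voxel targets and removes
a long burn-in phase.

Because of the residual input addition, the completion network's output on
existing bone is sigmoid + 1 > 1: the clip makes those voxels loss-free, so
bone present in the input is always preserved and learning concentrates on
the defect region and the background. The voxel-mean (rather than
voxel-sum) form of the loss was chosen because it makes loss values
comparable across grid sizes; with an adaptive optimizer the difference is
only a step-size scale.

Reference full-scale settings (1,200 epochs for completion, 20 for
enhancement, tens of thousands of training pairs) are documentation-level
configuration; the package defaults are desk-scale.

## Synthetic phantoms and defect simulation

No patient data ships with, or is needed by, the package. Phantoms are
closed ellipsoidal bone shells evaluated analytically at voxel centers:
outer semi-axes default to 72 x 88 x 60 mm with a 6 mm shell (adult-vault
scale), the right half is enlarged by an asymmetry factor (default 5%,
reflecting natural left-right skull asymmetry), and everything below a base
plane (default: the lowest quarter of the grid) is removed, mimicking
Frankfort-plane normalization. The implicit double-ellipsoid definition
gives an analytic volume oracle for testing. Dataset generation draws
phantom parameters uniformly from configurable ranges and pairs each
full-resolution shell with its 4x block-majority down-sampled companion.

Defects are parametric masks in four families — elliptical cylinder, mixed
elliptical cylinder (union of two cylinders with independent axes),
ellipsoid, and hybrid ellipsoid (ellipsoid ∪ cylinder about a shared
center); the published mask families are shown only as renderings, so the
union compositions here are this package's stated reading of those shapes.
The largest in-plane diameter is uniform over 60–120 mm (the clinically
representative craniectomy range), centers are uniform over the upper-skull
region, and 25 in-range defect variations are generated per intact skull.
"In range" means: non-empty removed part, entirely at or above the given
horizontal plane, and the remaining skull not broken into more than two
large (≥5% of remaining bone) 6-connected pieces — the published data
curation names the concept but not the rule, so the rule is defined here
and tested. Rotation augmentation produces 2·3 + 1 = 7 variants per model
at 2° steps about the craniocaudal axis, nearest-neighbour resampled so
volumes stay binary.

What the phantoms deliberately do not model: sutures, facial bones,
diploë/bone-density structure, scanner noise, and the uneven borders of
real craniotomies (masks are smooth parametric solids). Passing tests on
phantoms therefore demonstrates that the machinery — geometry, training
dynamics, metrics, extraction — is correct at desk scale, not that the
desk-scale network generalizes to clinical CT.

## Evaluation metrics

* **Sørensen–Dice index**: `2 N_TP / (2 N_TP + N_FP + N_FN) x 100%`,
  symmetric, 100 for identity.
* **Directed Hausdorff distance**: the largest distance from a bone voxel
  of the ground truth to the nearest bone voxel of the prediction (the
  directed form is primary, matching the definition used for the published
  results; a symmetric `hausdorff_distance()` is provided and labelled).
  Lattice units by default — on a 0.45 x 0.45 x 0.8 mm grid one unit spans
  0.45 to 1.0223 mm, see `hd_unit_range()` — or mm over spacing-scaled
  centers.
* **Cranial vault asymmetry indices**: on the axial plane that intersects
  the implant the most (ties to the inferior-most slice), four rays leave
  the midline point O at ±60° from the anterior Y direction; A/B are the
  anterior crossings, C/D the posterior ones, each the *outermost* 0.5
  crossing of the bilinearly interpolated contour. ACVAI =
  |AO − BO|/AO x 100%, PCVAI = |CO − DO|/DO x 100%. Magnitudes are
  reported (the published table prints positive values even where the
  second length is larger); the signed values are kept in an attribute.
  The construction of O is not published; here O sits on the midsagittal
  axis at the y centroid of the in-plane cross-section, a stated choice.

## Numerical choices

* HU window endpoints inclusive; prediction threshold inclusive (≥ 0.45).
* Lanczos order 3 with out-of-range samples clamped to edge values and
  weights renormalized to sum 1 (constants are exact fixed points).
* Binary resampling: interpolate as reals, threshold at 0.5;
  block-majority down-sampling counts exact half-occupancy ties as bone
  (deterministic and symmetric).
* Grid conventions: 0-based indices, (x, y, z) with z craniocaudal; the
  raw-uint8 dialect is x-fastest with a JSON sidecar.
* ReLU subgradient at 0 is 0; max-pool ties break to the first voxel in
  x-fastest order.
* Mesh export emits the exact 0.5 iso-surface of the binary field under
  nearest-neighbour interpolation (voxel-face triangulation): watertight by
  construction and volume-exact, at the cost of a stair-stepped surface —
  appropriate for fit checking; smooth fabrication surfaces are downstream
  CAD work.
* Implant scaling is nearest-neighbour about the occupancy centroid (the
  published procedure states only the 102% factor).

## Desk-scale study conditions

The self-contained training study used by the test suite runs the
completion network at 32 x 32 x 24 voxels of 6 x 6 x 8 mm (a 192 mm field,
4x coarser than the reference low-resolution grid but with the same
relative defect sizes): 16 phantom vaults x 5 defects = 80 training pairs,
2 unseen vaults x 5 defects = 10 held-out pairs, batch size 10, 140 epochs
(within the 200-epoch cap; the validation loss and held-out recovery
plateau around epoch 110), best-validation checkpoint. Defects are
restricted to the upper vault (in-range plane at mid-height) and curated
with the default graze rejection: a mask removing under 1% of the bone is
not a craniectomy-like defect, and on this coarse grid such grazes are
2-voxel slivers on which a Dice score is meaningless. Shell thickness for
this grid is drawn from 10–14 mm so the shell resolves to about two voxels
— below that, a voxelized shell stops being a single 6-connected
component, which is a representability constraint of the coarse grid, not
an anatomical choice; the finer default grid uses anatomical 5–8 mm
shells. Recovery is measured as the mean Sørensen–Dice index between the
extracted implant (threshold 0.45, tolerance scale 1.0) and the
ground-truth implant over the held-out pairs.

## Known limitations

* The desk-scale networks are trained on smooth analytic phantoms; no
  claim is made about clinical CT performance of weights trained here.
* The enhancement network's second input enters parameter-free (see the
  architecture section): the published narrative suggests a dedicated
  entry convolution, which is arithmetically incompatible with the
  published parameter total; we follow the total.
* Frankfort-plane indices and Hounsfield windows are user inputs; nothing
  is auto-detected.
* Voxel-face meshes are stair-stepped; no surface smoothing or thickness
  offsetting is provided.
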