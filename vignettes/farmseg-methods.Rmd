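---
title: "Methods: architecture, losses, synthetic scenes and accounting"
author: "farmseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: architecture, losses, synthetic scenes and accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(farmseg)
```

## What the package models

`farmseg` implements a family of lightweight anchor-free instance-segmentation
networks for agricultural imagery, together with everything needed to train,
evaluate and audit them on synthetic data. The family starts from a
nano-scale CSP backbone with an SPPF pooling pyramid, a PAN-FPN neck and
decoupled detection heads that regress boxes as discretized distance
distributions (reg_max = 16 bins per side), classify with per-class sigmoids,
and segment by linearly combining 32 shared prototype maps with per-instance
coefficients. Five variants are provided:

* `baseline` — three detection scales (strides 8/16/32);
* `p2` — an extra stride-4 scale and fourth head for small objects
  (a 160 x 160 grid at 640 x 640 input);
* `p2_cpca` — every neck C2f block replaced by C2f_CPCA;
* `p2_cpca1` — only the four head-adjacent C2f blocks replaced;
* `full` — `p2_cpca` plus a C3RFEM block inserted after SPPF.

The stride-4 scale exists because farmland scenes mix very large regions
(unharvested / harvested fields, lodging patches) with very small instances
(people at a distance): at stride 32 a person a few pixels wide simply
disappears, while the stride-4 grid keeps enough spatial detail and assigns
enough cells for such objects to be learned at all.

## Channel-prior convolutional attention

CPCA refines a feature map `F` (shape C x H x W) in two sequential stages:

    Fc = CA(F) * F          channel attention, C x 1 x 1 weights in (0, 1)
    Fb = SA(Fc) * Fc        per-channel spatial attention, C x H x W

`CA` pools `F` globally by average and max, passes both descriptors through a
shared MLP and squashes the sum: `CA(F) = sigmoid(MLP(avg) + MLP(max))`. `SA`
applies a depthwise 5 x 5 convolution, adds depthwise strip branches on top of
an identity branch, and finishes with a 1 x 1 mixing step whose raw output
multiplies `Fc` directly — no extra squashing, so spatial attention can both
attenuate and amplify. The spatial map is kept per channel (C x H x W): that
is the "channel-prior" reading, and it is what a 1 x 1 convolution over C
channels naturally produces.

Two geometries are available through `nn_cpca()`:

* **light** (default): the shared MLP is a *channel-shared* scalar bottleneck
  (8 hidden units, no bias, 16 parameters total), one strip pair of length 3,
  and a per-channel 1 x 1 mix. Total cost is exactly `33 C + 16` learnable
  scalars — linear in the channel count. This is what makes C2f_CPCA strictly
  lighter than the C2f block it replaces at every neck position, and it
  reproduces the deployed parameter budget of the architecture family that
  this package re-implements.
* **reference**: dense channel MLP with reduction 16 (hidden floor 8), strip
  pairs of lengths 7/11/21 and a dense 1 x 1 channel mix — the geometry of
  the original CPCA publication, at roughly 1.5 C^2 parameters. It is kept as
  a configuration preset for comparison studies.

With every parameter at zero the channel map is exactly 0.5 everywhere
(`sigmoid(0)`), which the tests assert as a degeneracy check.

**C2f_CPCA.** A C2f block splits its 1 x 1 projection into two hidden-width
halves, runs one half through `n` chained bottlenecks and concatenates
`(2 + n)` chunks before the fuse. C2f_CPCA no longer retains the direct copy:
the first half is refined by CPCA, the plain copy of the second half is
dropped, and `(1 + n)` chunks are fused. CPCA is applied after the split, on
the hidden-width branch — the narrowest point, which keeps the attention
cost minimal.

## RFEM and C3RFEM

RFEM enhances receptive-field diversity at the end of the backbone. The
package's block has four parallel branches on the same input: an
identity-path 1 x 1 convolution, and for each dilation d in {1, 2, 3} a
parameter-free depthwise 3 x 3 mean aggregation at dilation d followed by a
1 x 1 convolution. Branch outputs are summed, fused by a 1 x 1 "weighted
layer" with SiLU, and added back to the input through a residual connection
(which keeps gradients well-behaved and makes the block an exact identity
when its weights are zero). The dilated aggregations give the three branches
3 x 3, 5 x 5 and 7 x 7 composite receptive fields while every learnable
weight stays pointwise, so the block costs exactly `5 (C^2 + C)` parameters
— 82,560 at C = 128. Branch weighting is absorbed into the per-branch 1 x 1
convolutions rather than kept as separate softmax scalars; a separate scalar
gate would be redundant with the scale freedom those convolutions already
have.

C3RFEM embeds RFEM as the inner path of a C3 block (two 1 x 1 entry
branches, concat, 1 x 1 fuse, hidden width C/2) and is placed directly after
SPPF in the `full` variant, deepening the backbone where the receptive field
is already largest.

## Losses and assignment

Cells are assigned to ground truths by task alignment: candidates are cells
whose center lies inside a ground-truth box, scored
`t = score^0.5 * IoU^6`; the top 10 candidates per ground truth become
positives, and contested cells go to the higher alignment. The composite
loss is

    total = 0.5 * cls + 7.5 * box + 2.5 * mask + 1.5 * dfl

with `cls` a class-weighted binary cross-entropy over all cells, `box` the
mean `1 - CIoU` over positives, `dfl` the distribution focal term that
pushes probability mass onto the two bins bracketing each true distance, and
`mask` a per-instance binary cross-entropy of the composed prototype mask
against the ground-truth mask inside its box (normalized by box area). The
cls/box/mask/dfl sums are normalized by the batch positive count, the
convention under which positive and negative gradients stay commensurate.

Class imbalance is handled by inverse-log-frequency weights
`w_c = 1 / log(frequency_c + alpha)` (natural log), applied to the two
class-bearing terms: the classification entries of positive cells and each
instance's mask term. `alpha` defaults to 1.02 so that `frequency + alpha`
exceeds 1 for every class — weights stay positive and finite — and the
weights flatten toward uniform as `alpha` grows. Frequencies are instance
frequencies (the class-count table of the training set), not pixel
frequencies: the weighting compensates for how rarely a class is *seen*, and
instance counts are what the dataset statistics report.

Classification targets are binary (1 at the assigned class of a positive
cell). The quality-aware soft target of task alignment
(`align / max_align * max_IoU`, exposed by `tal_assign()`) was evaluated and
deliberately not used in the loss: over short training horizons it keeps all
scores near zero and ranking never emerges; with long schedules it is the
standard choice, and the hook is there for it.

Training uses AdamW (beta1 = 0.9, beta2 = 0.999), weight decay 5e-4 on
convolution weights, cosine annealing to 1% of the initial rate,
gradient-norm clipping at 10 and batch size 8. The production initial rate
is 1e-3, appropriate to multi-hundred-epoch schedules; short smoke runs (see
below) pass `lr0 = 0.01` explicitly, since AdamW moves each coordinate by at
most about `lr` per step and a few hundred steps at 1e-3 cannot reorganize
logits that start several units from their targets. For the same reason
`train_model()` offers `schedule = "cosine_restarts"` (5-epoch warm-restart
cycles): at 150-250 step horizons the repeated high-rate phases measurably
out-train a single monotone decay, while plain cosine remains the default
for production-length runs.

One implementation note: the gradient of the CIoU box term with respect to
the four decoded distances is taken by central finite differences (step 1e-3
of a stride) and then chained analytically through the softmax expectation
of the distance distribution. The CIoU expression is piecewise and its exact
derivative adds nothing but fragility at this cost scale; the finite
difference is exact to O(h^2) and is covered by the end-to-end gradient
checks in the test suite, which compare every other path analytically to
1e-6.

## Synthetic scenes

`generate_scene()` emulates the *structure* of 8-class harvest-season
imagery: large irregular star-convex regions for the area classes
(unharvested, harvested, farm, lodging), thin elongated strips for ridges
between fields, boxy mid-size polygons for harvesters, compact blobs for
obstacles, and rare small blobs (at least ~3 px radius) for people. Class
identity is carried mainly by colour, with per-instance shading jitter and
pixel noise (sd 0.03). Instance classes are drawn from the empirical
imbalance of the reference class-count table (people ≈ 3.1%, under the 5%
rarity constraint), which a Monte-Carlo test verifies to ±2% over 1,000
scenes. Instances are placed with overlap avoidance (a candidate polygon is
re-drawn when it would cover more than ~5% already-claimed ground, best of
eight tries kept): fields, ridges and machines do not overlap in real
scenes, and overlap-free placement also keeps the ground-truth masks fully
observable in the rendered image. Every instance keeps its full polygon and
rasterized mask (even-odd rule over pixel centers).

What the scenes do **not** emulate: photorealistic texture, occlusion
statistics, perspective, lighting gradients, motion blur, or
intra-class appearance variation. A model that segments these scenes has
demonstrated that the architecture, assignment, loss and decoding pipeline
are wired correctly and can fit colour-and-shape-separable classes — not
that it would reach any particular accuracy on real farmland imagery.

The augmentation pipeline mirrors the study conditions: every source image
yields four variants — original, linear contrast with gain 1.5 about the
per-image mean (preserving mean brightness), additive Gaussian noise with
sd 0.1 on the [0, 1] scale, and a horizontal flip with consistently
mirrored polygons and masks — so 593 sources become 2,372 images. The
fourfold expansion is fixed by that arithmetic; a "flip 50% of samples"
reading would produce a non-integer multiple. `split_dataset()` shuffles
under a seed and sizes splits as floor proportions of the item count
(remainder to training); when augmented variants carry a `source` index the
split assigns whole source groups to one split, trading exact quota sizes
for leak prevention.

The statistics helpers reproduce standard dataset-shift analyses: smoothed
256-level brightness histograms, Sobel gradient-magnitude distributions
(luma weights 0.299/0.587/0.114, interior pixels only, so a contrast gain
without clipping scales every magnitude exactly), and a 2-D PCA embedding of
image features. The default feature extractor is a fixed, seeded
random-projection bank over a 16 x 16 downsampling — dependency-free and
deterministic — and any `image -> vector` function can be plugged in
instead.

## Evaluation

`evaluate()` scores masks, not boxes: predictions are matched greedily in
descending score order against unmatched same-class ground truths of the
same image, a true positive requiring mask IoU at or above the threshold.
AP integrates the precision envelope over every achieved recall (all-point
interpolation); mAP averages over classes with at least one ground truth;
mAP@0.5:0.95 averages the ten thresholds 0.50 to 0.95. Two degenerate-case
conventions: the IoU of two empty masks is 1 (vacuous agreement), and the
single reported precision/recall pair per class is taken at the confidence
that maximizes F1 at IoU 0.5, since a single operating point is otherwise
undefined. The evaluator is cross-checked in the tests against an
independent oracle (explicit-loop matching, 10,001-point Riemann AP) to
1e-3 over 50 randomized cases.

## Accounting conventions

`count_params()` reports the deploy-time (fused) convention by default:
every Conv-BN unit counts its convolution weights plus one bias per output
channel, i.e. with the batch-norm affine pair folded into the convolution;
the 16 fixed expectation weights of the box decode layer are included.
`fused = FALSE` gives the raw training-time sum. Under the fused convention
the five variants count 3,259,624 / 3,175,632 / 3,133,056 / 3,140,096 /
3,347,200 parameters — the published budgets of the architecture family —
and the per-layer breakdown in `report_table()` localizes any mismatch.

`count_flops()` doubles per-layer multiply-accumulates (1 MAC = 2 FLOPs) at
the resolution each layer sees. The default `"profile"` convention counts
the standard convolution/linear layers of the graph — the convention of
mainstream layer profilers, which do not see inside custom blocks — giving
12.0 GFLOPs for the baseline and 26.0 for the full variant at 640 x 640.
The `"all"` convention additionally counts attention and RFEM internals,
pooling and activations for an everything-included estimate; the attention
internals are depthwise and add only ~0.07 GFLOPs at 640.

## Numerical choices

* Boxes are half-open pixel rectangles `[x1, x2) x [y1, y2)`, origin
  top-left; cell centers sit at `(i - 0.5) * stride`; masks rasterize over
  pixel centers.
* The instance-mask threshold is strictly greater than 0.5, so all-zero
  coefficients (`sigmoid(0) = 0.5`) give an exactly empty mask.
* Batch-norm uses eps 1e-3 and running-statistics momentum 0.03; evaluation
  mode uses the running statistics.
* Max-pool ties resolve to the first index (deterministic backward).
* Duplicate suppression at decode time is class-wise and *mask-based*:
  candidates are compared by composed-mask overlap (at prototype
  resolution), not box overlap, and empty-mask detections are dropped. For
  a segmentation decoder the masks are the well-localized quantity; with
  box-based suppression, sloppy boxes of adjacent region instances suppress
  each other long before their masks actually overlap. Decode defaults:
  confidence 0.25, suppression IoU 0.7, 300 detections; mAP evaluation
  should use a low confidence threshold (0.01) so the full PR curve is
  scored.
* All randomness flows through R's RNG; `set.seed()` before building or
  generating makes builds, scenes and training bit-reproducible on one
  machine.

## Problem sizes used by the checks

The test suite exercises oracles at deliberately small sizes (blocks at
4-16 channels, evaluator cases on 16 x 16 canvases) and runs one seeded
smoke training of the `full` variant: 48 training and 16 validation scenes
at 64 x 64 (4-7 instances each), 30 epochs with warm-restart cycles, batch
8, `lr0 = 0.01`, validation decoding at confidence 0.01, two seeds. These
sizes are the
package's own choice of a minimal configuration at which the end-to-end
claim — the composite loss at least halves and held-out mask mAP@0.5
exceeds 0.5 — is stably reproducible; the same pipeline runs unchanged at
larger scene counts, resolutions and epoch budgets via `train_model()`.

## Known limitations

* The training engine is a single-machine, CPU, double-precision
  implementation built for correctness and auditability; it is suitable for
  smoke-scale experiments, not for full-scale training runs.
* Synthetic scenes are colour-separable by construction (see above).
* The `"all"` FLOP convention approximates activation cost as one operation
  per output element.
* Checkpoint import from other frameworks is out of scope; models are built
  and trained within the package.
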