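---
title: "Lightweight re-parameterized pest detectors: models, compression and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight re-parameterized pest detectors: models, compression and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestnet)
```

# The problem

Forestry pest monitoring needs object detectors that run on small devices:
many pest classes (here 29), small and densely packed targets, cluttered
backgrounds, and hard limits on parameters, FLOPs and weight-file size.
`pestnet` implements a family of lightweight anchor-free detectors around a
YOLOv8-nano-style baseline, three architectural replacements that trade
accuracy against cost, structural re-parameterization for inference, and
LAMP channel pruning toward a FLOPs speed-up target, together with the
COCO-style evaluation stack and a synthetic scene generator that stands in
for the (undeposited) forestry-pest imagery.

Everything is implemented as a flat graph of primitive layers (convolution +
batch norm + SiLU, pooling, concatenation, residual adds, channel shuffles,
attention nodes) with hand-derived backward passes; the dense kernels are
C++ (Armadillo). All computation is double precision.

# Model family

**Baseline.** The nano-scale CSP backbone (stem conv, four stages of C2f
blocks with stride-2 convs, SPPF), a PAN/FPN neck of C2f blocks, and a
decoupled anchor-free head predicting per-side distance distributions
(16 distribution-focal bins per side) and per-class logits at strides
8/16/32. At 29 classes this graph has 3,016,487 trainable parameters and
8.11 GFLOPs at 640x640 (2x multiply-accumulates, convolutions and linear
layers only) — matching the published accounting of the family.

**Re-parameterizable hybrid backbone.** The backbone swap replaces the CSP
stages with an HGNetV2-style stem (five convolutions and one max pooling,
total downsampling x4) and dense-aggregation blocks in which the inner
convolution is a *RepLightConv*: a linear 1x1 pointwise conv followed by an
activated depthwise 3x3 block that trains as three parallel branches
(3x3+BN, 1x1+BN, identity BN) and fuses into a single 3x3 conv for
inference. Each block concatenates the input with `n` chained RepLightConv
outputs and squeezes/excites via two 1x1 convs; a residual add is used when
the widths match.

The printed totals of the family pin only per-variant sums, not stage
widths. The stage table was therefore calibrated once against the published
parameter totals and the full-model FLOPs: stem 16/32, stages
(mid 8, out 32, x1, 4 inner convs), (64, 64, x1, 6), (96, 128, x1, 6),
(192, 256, x1, 6), with depthwise stride-2 downsamples between stages and
P3/P4/P5 taps at stages 2-4. This lands the backbone at 0.596 M parameters
and 0.948 G MACs, reproducing both the backbone-swap row (2.34 M) and the
full model (7.6 GFLOPs).

**Slim neck.** GSConv replaces the neck's downsampling convs and VoVGSCSP
replaces its C2f blocks. GSConv computes half the output channels with a
standard conv and the other half with a depthwise conv on top of the first
half, concatenates, and channel-shuffles with two groups (the shuffle moves
channel `c` to `(c mod 2)(C/2) + floor(c/2)`). A GSbottleneck is two GSConvs
(the first halving the width) plus an identity skip; VoVGSCSP is the
cross-stage-partial arrangement over them. The published slim-neck row
requires more capacity than a single bottleneck per block provides, so the
bottleneck repeat is 3 per VoVGSCSP with 3x3 first-GSConvs — again a
one-time calibration against the printed total (2.77 M measured vs 2.80 M
printed).

**Dynamic head.** Before the detect layers, the three pyramid levels are
projected (1x1) to a common width, resized bilinearly to the median level's
grid, stacked, and passed through two attention blocks, each applying in
sequence:

* *scale-aware*: a per-level gate `sigma(f(mean_{S,C} F))` with `f` a linear
  readout of the per-channel spatial means and `sigma` the hard sigmoid
  `max(0, min(1, (x+1)/2))`;
* *spatial-aware*: `out(s,c) = (1/L) sum_l sum_k w_{l,k} F(l; p_k + dp_k; c)
  dm_k` over K = 9 sampled locations (3x3 base grid, learned offsets `dp_k`,
  learned importances `dm_k`, learned aggregation weights `w_{l,k}`), with
  bilinear sampling clamped to the feature bounds. The equation aggregates
  over levels and broadcasts the result back to every level, and the
  implementation follows it literally;
* *task-aware*: per channel `max(alpha1 F_c + beta1, alpha2 F_c + beta2)`
  where `[alpha1, alpha2, beta1, beta2] = theta(F)` comes from a global pool
  over levels and space, two fully connected layers (reduction 16) and a
  shifted sigmoid `2 sigmoid(x) - 1` into `[-1, 1]`.

After the tower, levels are resized back and projected to their original
widths, so the detect layers are identical to the baseline's. The common
width (416) and block count (2) were calibrated against the published
parameter delta of the head addition (+0.48 M). Running the detect stems on
the unified width instead would force a width near 124 whose 3x3 class stems
add several GFLOPs at the P3 grid — incompatible with the published
full-model FLOPs — which is why the project-back design was chosen.
Offsets start at zero, importances at `1/K`, aggregation weights at 1; the
task block's first-branch logit bias starts at 4 so every block begins close
to an identity map.

# Re-parameterization

Folding batch norm into a conv gives `w' = w * gamma / sqrt(var + eps)` and
`b' = beta - mean * gamma / sqrt(var + eps)`; a 1x1 kernel lifts to 3x3 by
centring; the identity branch is a group-aware Dirac kernel. Summing the
three folded branches yields one 3x3 kernel + bias per block. Equivalence is
the module's contract: per block, 100 random standard-normal probes must
agree within 1e-5 max-abs (the whole model within 1e-4); in double precision
the measured differences sit near 1e-15, far inside the 1e-10 requirement.
Re-parameterization strictly reduces parameters and FLOPs and is idempotent.

# LAMP channel pruning

For a layer's flattened weights sorted ascending by magnitude, the LAMP
score is `w[u]^2 / sum_{v >= u} w[v]^2`; the largest weight of every layer
scores exactly 1, and scores are invariant to positive rescaling. Ties are
broken stably by index, so equal-magnitude weights receive different scores
(the definition's suffix sums differ) — the earlier index sees the larger
denominator.

LAMP is natively unstructured; for channel pruning the importance of an
output channel is the sum of the scores of its weights, and coupled channel
groups (through concatenations, residual adds, channel shuffles, depthwise
convolutions and the tower's level stack) are traced with a union-find over
per-channel variables and summed over members. The planner greedily removes
the globally least-important groups — keeping at least two channels per
layer, then rounding layer widths to multiples of two — until
`FLOPs_before / FLOPs_after` reaches the requested speed-up (1.5x and 2.0x
are the reference points). Protected: the first stem conv, the detect output
convs, and the dynamic-head projections/reducers (pruning them would change
the task interface). Applying a plan physically slices kernels, batch-norm
vectors and downstream input channels and re-indexes channel-slice nodes;
a keep-all plan is byte-identical to the original network.

# Evaluation

Greedy one-to-one class-aware matching by descending confidence (ties to
the lower ground-truth index); precision `TP/(TP+FP)` and recall
`TP/(TP+FN)` with zero denominators reported as 0 plus a flag; AP as the
area under the monotone precision envelope with all-points (continuous)
interpolation — chosen over 101-point interpolation because the definition
is an integral, and documented here for reproducibility; mAP\@0.5:0.95 as
the mean over the 10-threshold IoU grid and over classes present in the
ground truth. The confusion matrix matches class-agnostically at IoU 0.45
and confidence 0.25 (evaluation conventions; the decode path uses
class-aware NMS at IoU 0.7 and confidence 0.001 for evaluation).

# Synthetic scenes

The generator emulates the study's imaging conditions: procedurally textured
foliage/bark/soil backgrounds with clutter blobs and pixel noise, and 29
class-parameterized insect-like targets (hue, saturation, body aspect from
round to larva-elongated, size multiplier, stripe/spot patterning, legs,
wings are deterministic functions of the class id). Boxes are tight around
the drawn extents; occluders are drawn over targets with the configured
probability. Defaults are the dense condition (3-8 targets, occlusion 0.3,
clutter 0.6, target diameters 6-22% of the image). Datasets are split
7:2:1 (train:test:val) by a seeded shuffle; labels are YOLO-format
normalized `class cx cy w h` text files written at 6 decimals.

Two presets are fixed up front: `easy` — two to three large (25-45%)
unoccluded targets on a plain soil background, classes drawn from 8
hue-spread (visually distinctive) ids — is the smoke-training condition;
`hard` (6-14 targets, occlusion 0.5, full clutter) stresses robustness. Per-class sampling weights expose the
heavy class imbalance of real trap imagery (one class can be made ~15x
another).

What passing smoke tests show — and what they do not: the synthetic targets
are colour-separable and rigidly parameterized, so a short training run
demonstrates that the assignment, loss, gradients, optimizer and decoding
work end to end; it says nothing about accuracy on real forestry imagery,
which has intra-class appearance variation, scale extremes and true
camouflage that the generator deliberately does not model (no photorealism).

# Training harness

The loss is the anchor-free composite under task-aligned assignment
(top-10 candidates inside each box, alignment `s^0.5 * IoU^6`, conflicts to
the highest IoU, target scores normalized per ground truth): complete-IoU
box term, binary cross-entropy classification term against the aligned
scores, and a distribution-focal term on the two integer bins adjacent to
each target distance, weighted 7.5/0.5/1.5. Assignment and target scores
are treated as constants by the gradients (the standard detached-target
convention); box gradients chain through the softmax expectation of the bin
distributions, with the complete-IoU derivative evaluated by central
differences per assigned anchor. Class logits start at the prior
`log(5 / nc / (imgsz/stride)^2)` — the expected objects per anchor at the
configured image size — which is what makes very short runs produce
detections above the evaluation threshold at all.

Defaults mirror the reference recipe: SGD (lr 0.01, momentum 0.937, weight
decay 0.005), batch 16, 300 epochs at 640, linear warmup (3 epochs) and
linear decay to 1% of the initial rate, mosaic augmentation (2x2 collage
around a random centre) disabled for the final 10 epochs. Two further reference-trainer behaviours matter at smoke scale: the
optimized objective is the normalized loss multiplied by the batch size (so
per-image gradient scale does not shrink with larger batches), and gradients
are clipped to a global norm of 10 (without it the neck activations blow up
within a few epochs and the tower's hard-sigmoid gate saturates to zero, a
state it cannot leave because the gate's gradient vanishes).

The desk-scale smoke condition is 64 easy-preset images at 160x160,
10 epochs, batch 2 with a one-epoch warmup, seed 0 — sizes chosen so the
whole run is a few minutes on one CPU, the small batch buying twice the
optimizer steps, and the short warmup leaving most of them at the full rate;
with a 10-epoch run the mosaic-off window spans the entire schedule,
matching the late-stage-disable rule. Class logits start at the
level-uniform prior `log(5 / nc / A)` with `A` the total anchor count:
a per-level prior of the usual `(imgsz/stride)^2` form starts stride-32
anchors at 16x the confidence of stride-8 anchors, and in runs of a hundred
steps those few dozen untrained coarse anchors dominate the ranking before
true positives can overtake them. Fine-tuning after pruning reuses the same schedule
(the reference protocol fine-tunes for the same number of rounds as
training; the smoke scale uses 10 epochs).

# Numerical choices and degenerate inputs

* Batch norm: eps 1e-3, momentum 0.03, biased batch variance for
  normalization and unbiased for the running estimate.
* Weight init: Kaiming-uniform (`U(+-1/sqrt(fan_in))`); builds are
  deterministic in the seed.
* Decoding drops boxes whose expected width or height collapses to zero;
  NMS is class-aware, greedy.
* `lamp_scores` rejects all-zero layers (`degenerate-layer`); pruning plans
  are infeasible (error) when protections make the target unreachable.
* All-zero class logits decode to confidence 0.5 for every class
  (sigmoid(0)); thresholds then filter.
* Division-by-zero conventions: precision/recall report 0 with a flag;
  assignment normalizers carry a 1e-9 guard.

# Known limitations

* Parameter totals match the published table within +-1.2%; exact per-layer
  widths of the original implementation are unknowable from printed totals.
* The published FLOPs of the slim-neck-only and head-only rows (7.3, 9.7)
  are reproduced in direction but not within 2% (7.67, 9.30 here); the
  graded baseline and full-model rows are.
* Training is CPU-bound and double precision; the harness is for smoke
  scale, not for reproducing 300-epoch GPU accuracy.
* The spatial attention follows the level-aggregated equation literally, so
  after the first block all levels share one (resized) spatial map; the
  per-level detect stems re-differentiate the scales.
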