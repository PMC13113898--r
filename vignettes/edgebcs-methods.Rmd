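---
title: "Models and methods behind edgebcs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind edgebcs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`edgebcs` builds, profiles and trains lightweight single-stage detectors for
beef-cattle body condition scoring (BCS) from dorsal tailhead imagery. This
vignette explains the models, the choices made where the design was open, the
numerical conventions, and what the synthetic experiments do and do not show.

## The task and the architecture family

One image contains one animal; the label is an axis-aligned box over the
tailhead region plus a condition class (BCS 3–7, five classes). The base
architecture is the published YOLO11 nano topology: a C3k2/SPPF/C2PSA
backbone producing feature pyramids at strides 8/16/32, a PAN neck, and a
decoupled anchor-free head with distribution-focal box regression
(`reg_max = 16` bins per side). Three substitutions define the full model:

**Coordinate attention.** Global pooling is factorized into two directional
1-D averages, which keep position along one axis each. A shared 1×1
transform (with BN and hard-swish) compresses the concatenated descriptors to
`max(8, C/32)` channels — the reduction ratio 32 with a floor of 8 follows
common practice for this attention family; both are exposed in
`ca_module()`. Two restoring 1×1 convolutions (with bias; no BN, since a
logistic gate follows directly) produce the gates. The gates multiply the
input elementwise, so attention output is always bounded by the input and a
zero input maps to zero. BN uses running statistics at inference, which is
also the deterministic mode the tests run in.

**Star blocks and TASM.** The star operation `relu6(W1x+b1) ⊙ (W2x+b2)`
realizes pairwise feature products — an implicit second-order polynomial
map — which is the mechanism for amplifying low-contrast fat texture. In the
exact-arithmetic limit (no bias, identity depthwise convolutions, inputs in
the ReLU6 linear region) the core is homogeneous of degree 2, a property the
tests verify numerically. The 7×7 depthwise convolution before the core
carries BN; the one after it deliberately does not, so the reconstructed
high-frequency response is not re-normalized; convolutions without a
following BN carry biases, those with BN do not. TASM keeps the C3k2
split/merge skeleton (1×1 expansion, a chain of units with every
intermediate retained, 1×1 merge) and swaps only the bottleneck units for
star blocks.

**PSFF neck.** Fusion nodes replace channel concatenation:
`F = CA(L) ⊙ σ(Conv₁ₓ₁(U)) + U`, where `L` is the lateral (skip) stream —
calibrated by coordinate attention — and `U` the resampled incoming stream
that provides the gate. The published description fixes the ingredients (CA
on laterals, multiplicative gating by high-level semantics, addition,
constant channels) but not the composition order; the form above satisfies
all of them and is frozen as the package's single fusion formula. The gate is
one 1×1 convolution per node (not per-channel scalars). The neck runs at one
constant width across all three levels — this is what "constant channel
dimensions" has to mean for the published size reduction (5.2 MB to 3.7 MB
from the neck change alone) to be arithmetically possible — with 1×1
adapters bridging the backbone's lateral widths. Upsampling is a learned
stride-2 transposed convolution (kernel 2; any constant partition-of-unity
stencil keeps constants constant, so no checkerboard artifacts on flat
regions), downsampling a stride-2 3×3 convolution.

**EGDH head.** Per level: a stem of two grouped 3×3 conv+BN+SiLU layers with
the group width fixed at 16 channels (`g = C/16`; a 1×1 adapter lifts
non-multiple widths), fused with the identity through a learnable scalar α
(one per level, initialized to 1), one grouped 3×3 conv+BN refinement, and
two bias-only 1×1 prediction convolutions. No normalization touches the
predictions, and every conv+BN pair folds exactly into a single convolution
at inference (`fuse_conv_bn()`, applied groupwise). Box encoding is
distribution-focal over 16 bins per side, matching the baseline head it
replaces. Prediction biases are initialized to the family's sparse-foreground
prior (classification) and to one (box bins).

## Complexity accounting

The profiler propagates shapes through every module and counts
multiply-accumulates ×2 for convolutions, transposed convolutions and linear
maps on the conv-BN-fused inference graph; explicit elementwise fusion
operations (gate products, residual adds, the star product) count one FLOP
per element; activations, bias additions, pooling, and the attention stage's
parameter-free activation–activation matrix products are not counted. This
single frozen convention reproduces the published 6.3 GFLOPs for the
five-class baseline and is used unchanged for every variant. Parameter
counts are taken on the training graph (BN affines included), which is what
a checkpoint stores; FP16 size is two bytes per parameter plus a small flat
container header, measured by actually writing the file.

The architecture's free widths — star expansion ratio (3.25 in the shallow
stages, 1.0 in the deep `c3k` stages, which hold most parameters but little
compute), the neck width (64) and per-stage star repeats (2,1,1,1) — were
calibrated once against the published complexity budget of the full model
(4.7 GFLOPs, 3.3 MB) by the grid search in `scripts/calibrate.R`, and frozen.
With them the ablation ladder is monotone as published: 6.32/5.18 (baseline)
→ 5.53/3.87 (+PSFF) → 5.62/3.63 (+TASM) → 4.69/3.30 (full).

## Training at desk scale

The loss is the YOLO-family composite: complete-IoU box loss, binary
cross-entropy classification with task-aligned soft targets, and
distribution-focal regression toward the two integer bins flanking each
target distance, weighted 7.5/0.5/1.5. Targets come from a task-aligned
assigner (candidates are anchors inside the box across all levels, ranked by
`score^0.5 · IoU^6`, top-10, conflicts to the best-aligned box; for boxes
smaller than one cell the nearest anchor per level is used). Classification
normalizes by the clamped sum of target scores; box and DFL terms use the
assignment scores as a weighted mean so localization keeps its gradient
scale while scores are still small.

The optimizer is SGD with momentum 0.937 and weight decay 5e-4 (applied to
convolution weights only, not biases or normalization affines), initial
learning rate 0.01 decayed linearly to 1% with a short linear warmup, and a
global gradient-norm safety clip at 100. Augmentations follow the published
recipe: HSV jitter 0.015/0.7/0.4, translation 0.1, scale 0.5, horizontal
flip 0.5, and four-image mosaic with probability 1.0 throughout training.

**Batch normalization at batch size one.** Desk-scale training processes one
image at a time, so the batch statistics are the image's spatial moments —
exactly what standard BN computes at batch size one. Normalization does real
optimization work here: freezing the statistics instead (normalizing with
the running moments during training) measurably stalls learning, because a
deep untrained stack then amplifies per-image scale dispersion — the star
operation is quadratic and compounds it — and no renormalization intervenes.
Training therefore uses per-image batch statistics, with the running moments
tracked as usual (after a short calibration pass that sets them to the exact
average over up to 16 sample images). A consequence of single-image batches
is that the network is fit under per-image normalization, so the training
loop's internal validation evaluates in the same mode
(`evaluate_model(use_batch_stats = TRUE)`); the deployable inference graph —
running statistics, conv-BN fusion — is exercised and checked separately by
the unit tests. The choice of optimizer follows the family's auto rule:
AdamW for runs under 10k iterations, the stated SGD settings otherwise (a
full-scale 100-epoch run on the field dataset is ~50k iterations, so the
published SGD configuration is what the rule selects there); the overfit
check pins SGD explicitly since its schedule is part of the check's
conditions.

## Distillation

The focal branch weights the squared teacher–student feature difference by a
binary foreground mask (cells whose centers fall in a box), a scale mask
(foreground weight is the reciprocal of the smallest covering box's area in
cells; background weight the reciprocal of the background area), and
tempered-softmax spatial/channel attention masks derived from the teacher
(temperature 0.5); an L1 term pulls the student's attentions toward the
teacher's. The global branch matches attention-pooled, parameter-free global
context vectors. Default weights (1.6e-3, 8e-4, 8e-4, 8e-6) follow the cited
focal+global method; this loss algebra is the package's largest
reconstruction from a citation, since the source paper describes the
strategy only qualitatively. All three neck levels are distilled with masks
recomputed per level; a trainable 1×1 adapter bridges any student–teacher
channel mismatch on the student side. None of this touches the inference
graph, which the tests assert.

## Synthetic data

The generator emulates the acquisition protocol: per animal, eight retained
frames per morning/evening session (bright vs. dim gain), one textured
body ellipse per frame on a structured background, a tailhead sub-box whose
local texture amplitude increases with the condition class, directional
motion blur (normalized line kernels, lengths 21–32, the 35 px kernel being
a stress-evaluation setting, applied before any resize) on roughly one third
of each animal's images, and a leak-free 8:2 animal-level split within each
class (round-half-up with a one-animal validation floor). Class proportions
follow the herd (17/82/174/198/23 of 494). A `zoom` argument models
acquisition distance: at the nominal hover the tailhead box is ~12% of the
frame, which at 640 px input spans ~10 stride-8 cells; desk-scale inputs of
64–128 px would shrink that to about one cell and degenerate anchor
assignment for reasons of input scale rather than of the method, so the
end-to-end training checks use close-up frames (`zoom = 2.5`, box ≈ 30% of
frame) that restore the study's object-to-cell geometry.

What passing these tests shows: the blocks compute their stated functions,
gradients are correct, the assignment/loss/decode/NMS/mAP chain is coherent
end-to-end, and the complexity arithmetic matches the published budget. What
they cannot show: detection accuracy on real cattle. The synthetic frames
lack occlusion, multiple animals, perspective, fur/lighting interactions and
annotation noise, and the texture-amplitude class code is a caricature of
real fat-cover appearance.

## Numerical choices and conventions

* AP integrates the precision envelope at 101 recall points (the COCO
  convention); the source prints only the integral.
* NMS is class-aware, greedy by confidence, ties broken by earlier index;
  matching uses each truth at most once, best IoU above the cut.
* Zero-area boxes score IoU 0 rather than NaN; degenerate inputs error.
* BN epsilon 1e-3, momentum 0.03; conv-BN fusion guards zero variance by the
  same epsilon.
* Checkpoints store every learnable tensor as IEEE binary16
  (round-to-nearest-even) in a flat uncompressed container.
* Reported problem sizes: profiler runs at the native 640×640; training
  checks use 32 images at 96×96 with a width-0.125 model, sizes chosen so
  the whole suite runs comfortably on one CPU.

## Known limitations

* Single-image SGD differs from large-batch training dynamics; the training
  loop validates mechanics and desk-scale convergence, not final-accuracy
  claims.
* The published mAP/precision/recall on the private cattle dataset are out
  of reach by construction (no data, no GPU-scale training) and are not
  asserted anywhere.
* The FLOP convention is one of several defensible ones; it is frozen and
  documented rather than per-model tuned.
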