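# edgebcs

Lightweight detection networks for image-based beef-cattle **body condition
scoring** (BCS), in pure R.

Body condition — the animal's subcutaneous fat reserve, scored 1–9 — is a key
welfare and management indicator in beef herds. It can be read from dorsal
images of the **tailhead region**, which turns scoring into a single-object
detection problem: localize the tailhead box and classify its condition
(classes 3–7 in commercial herds). Edge deployment on farms demands very small
models, which this package builds and studies.

`edgebcs` implements and profiles a family of detectors derived from the
YOLO11-nano architecture:

* **Coordinate attention (CA)** — channel attention factorized into two 1-D
  directional pools, `z_h[c,i] = mean_j x[c,i,j]` and
  `z_w[c,j] = mean_i x[c,i,j]`, passed through a shared 1×1 transform (BN +
  hard-swish), split, restored, and applied as two logistic gates:
  `y[c,i,j] = x[c,i,j] · g_h[c,i] · g_w[c,j]`.
* **Star texture blocks / TASM** — 7×7 depthwise pre-convolution (BN), two
  parallel 1×1 expansions fused by `relu6(W1x + b1) ⊙ (W2x + b2)` (an implicit
  second-order feature map), 1×1 projection, 7×7 depthwise post-convolution
  (deliberately without BN), residual add. TASM mounts these inside the C3k2
  split/merge skeleton in place of the standard bottlenecks.
* **PSFF neck** — constant-channel gated fusion instead of channel
  concatenation: `F = CA(L) ⊙ σ(Conv₁ₓ₁(U)) + U` at every pyramid node, with
  learned transposed-convolution upsampling and stride-2 convolution
  downsampling.
* **EGDH head** — grouped-convolution stem (group width fixed at 16, so
  `g = C/16` and FLOPs drop by `1/g`), learnable-α identity residual, one
  grouped refinement layer, and bias-only 1×1 prediction maps that fuse BN
  losslessly at inference.
* **FGD distillation losses** — foreground-focused (binary/scale masks,
  tempered-softmax spatial and channel attentions) plus global-context feature
  matching between a frozen teacher's and the student's neck maps;
  training-time only.

Everything runs on a small reverse-mode autodiff core with compiled
(Rcpp/RcppArmadillo) convolution kernels, so the networks are trainable on a
CPU at desk scale. The package also ships the dataset-construction rules
(1-in-3 frame thinning, 21–32 px directional motion-blur augmentation,
leak-free animal-level 8:2 splitting), a synthetic fixture generator, and the
full detection metric stack (IoU, class-aware NMS, P/R, 101-point AP,
mAP@50, mAP@50:95, theoretical FPS).

## Worked example

```r
library(edgebcs)
set.seed(1)

full <- build_model(model_config("full"))
full
#> edgebcs detector [full]  nc=5  params=1,647,626  GFLOPs(640)=4.69  fp16=3.3 MB

base <- build_model(model_config("baseline"))
base
#> edgebcs detector [baseline]  nc=5  params=2,590,799  GFLOPs(640)=6.32  fp16=5.2 MB
```

The full model runs at 4.69 GFLOPs and 3.3 MB — a 26% compute and 36% size
reduction over the 6.32 GFLOPs / 5.2 MB baseline, at equal input resolution
and class count. `complexity_report()` returns the per-module table behind
these numbers.

A small end-to-end run on synthetic data:

```r
ds  <- generate_synthetic_dataset(8, images_per_session = 2, blur_fraction = 0,
                                  seed = 11, width = 96, height = 96, zoom = 2.5)
tiny <- build_model(model_config("full", width = 0.125))
cfg  <- train_config(epochs = 150, batch = 8, imgsz = 96, augment = FALSE, seed = 11)
res  <- train(tiny, list(images = ds$images, labels = ds$labels), cfg, eval_every = 25)
res$best_map50   # mAP@50 on the training images - the overfit sanity check
```

Latency bookkeeping uses the theoretical-throughput identity:

```r
theoretical_fps(13.26)
#> [1] 75.41
theoretical_fps(12.40)
#> [1] 80.65
```

A thin command-line front end lives at `inst/cli/edgebcs.R`
(`synth`, `blur`, `profile`, `train`, `eval` subcommands).

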