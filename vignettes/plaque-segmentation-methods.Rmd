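---
title: "Segmenting carotid plaques in ultrasound with HRU-Net: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting carotid plaques in ultrasound with HRU-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Atherosclerotic plaques protrude from the carotid artery wall into the
lumen; their size and morphology on B-mode ultrasound drive stroke-risk
assessment. Delineating plaques by hand is slow and rater-dependent, and
automatic segmentation is hard for three reasons: plaques are heterogeneous
between and within patients; ultrasound is contaminated by multiplicative
speckle, acoustic shadows and reverberation artifacts that mimic plaque
texture; and the boundary between plaque and a thickened intima–media
complex is often ambiguous. Labelled clinical images are scarce, so the
network and the training protocol are both built around small-sample
regularisation.

`plaqueseg` implements the full HRU-Net recipe: an ImageNet-transferable
ResNet-50 encoder under a U-Net-style decoder, hybrid atrous convolution
(HAC) modules on the deep semantic layers, mask-consistent geometric
augmentation including a cropped-blood-vessel (CBV) prior, a class-weighted
Dice loss, k-fold cross-validated training with softmax-averaged
ensembling, and a Dice/IoU/accuracy/MHD evaluation suite.

## Network architecture

The encoder is a standard ResNet-50: a 7×7 stride-2 stem (64 channels),
then bottleneck stages of 3/4/6/3 residual blocks producing
256/512/1024/2048 channels at 1/4 … 1/32 of the input resolution. Each
residual block computes `y = F(x, W) + x` with a 1×1–3×3–1×1 bottleneck;
the first block of each stage carries a projection shortcut. Because the
decoder does not need thousand-channel skips, every stage output passes a
1×1 convolution (with batch norm and ReLU) that reduces the widths to

| stage      | resolution | channels | reduced |
|------------|-----------:|---------:|--------:|
| conv block | H/2 × W/2  | 64       | 32      |
| res1       | H/4 × W/4  | 256      | 64      |
| res2       | H/8 × W/8  | 512      | 96      |
| res3       | H/16 × W/16| 1024     | 128     |
| res4       | H/32 × W/32| 2048     | 128     |

The decoder mirrors the reduced widths (128, 128, 96, 64, 32): each stage
bilinearly upsamples ×2, concatenates the matching reduced skip, and
applies two 3×3 conv/BN/ReLU layers; a final ×2 upsample and a 1×1
convolution produce two-channel logits at full input resolution, closed by
a per-pixel softmax. Inputs must therefore be divisible by 32 in both
dimensions; grayscale images are replicated to three channels so the stem
keeps the pretrained-weight shape.

### Hybrid atrous convolutions

A dilated 3×3 convolution with rate *r* spaces its taps *r* pixels apart,
enlarging the receptive field without extra parameters; a stride-1 cascade
with kernel sizes *K<sub>i</sub>* and rates *r<sub>i</sub>* sees
`RF = 1 + Σ r_i (K_i − 1)` pixels, so the rate-1→2→3 chain of 3×3 kernels
sees 13×13 (`receptive_field(c(3,3,3), c(1,2,3))`, cross-checked in the
tests by measuring the nonzero extent of an impulse response through the
actual convolution cascade). A HAC block runs four parallel dilated 3×3
branches at the small rates 1, 2, 3, 5 next to that cascaded chain, each
branch conv/BN/ReLU at the input width.

How the five branches fuse is an open design point; we concatenate the
branch outputs along channels and apply a 1×1 conv/BN/ReLU back to the
input width. This keeps every HAC channel- and resolution-preserving, so
blocks can be dropped onto any layer — which the ablation harness needs.
By default HACs sit on the three deep semantic layers (the reduced res2,
res3, res4 features, before skip concatenation); `hac_placement_for_count()`
extends the placement down the skip hierarchy (res1, conv block, and
finally the full-resolution decoder stage) for the 1–6 module sweep, and
an empty placement yields the plain RU-Net baseline.

### Transfer learning

`load_pretrained_encoder()` initialises the stem and all bottleneck blocks
from a named list of parameter arrays (e.g. ImageNet-trained ResNet-50
weights exported from any source); shapes are validated per block and all
parameters remain trainable, i.e. fine-tuning at the default learning rate
1e-4. Without a weight source the encoder keeps its seeded He-normal
initialisation — that is the configuration every test in this package
runs, so the test suite exercises the architecture and optimisation, not
the transfer effect itself.

## Augmentation

Training images (never test images) are expanded eightfold:

* **GIA** — six geometric variants: identity, horizontal flip, vertical
  flip, 180° rotation, and ±30° rotations. Labels undergo exactly the same
  transform.
* **CBVIA** — the image multiplied elementwise by the binary vessel
  (adventitia) mask, plus the vertical flip of that product. Because
  plaques exist only inside the vessel, the CBV image carries a position
  prior; a plaque-label pixel outside the vessel mask raises an error
  rather than being silently clipped.

So 40 originals become 320 training pairs (240 GIA + 80 CBVIA), and a
36-image cross-validation training split becomes 288. The ±30° rotations
keep the original canvas, fill uncovered corners with 0, and resample
bilinearly for images but nearest-neighbour (re-binarised at 0.5) for
labels, so labels stay strictly binary; the rotation backend is
`EBImage::rotate()`. Intensity augmentations and elastic deformations are
deliberately out of scope.

## Loss, optimisation and cross-validation

The loss is a class-weighted Dice loss over the background/plaque one-hot
channels,

$$L = \sum_{e\in\{0,1\}} C_e\left(1 - \frac{2\sum_{m,n} L_e S_e}
{\sum_{m,n} L_e + \sum_{m,n} S_e}\right),$$

with \(C_0 = C_1 = 0.5\) by default; a smoothing constant of 1e-6 in each
denominator keeps images with an empty class finite (the reference
protocol does not state one). Optimisation is Adam
(β₁ = 0.9, β₂ = 0.999, ε = 1e-8) at learning rate 1e-4 for 100 epochs with
batches of 4, no schedule and no early stopping. `make_folds()` deals
samples round-robin after a seeded shuffle, so with 40 images and k = 10
every fold holds out exactly 4; held-out images are evaluated un-augmented.
For new images the k fold models are combined by averaging their softmax
maps pixelwise before the arg-max (`ensemble_predict()`); averaging in
probability space keeps the result normalised and reduces fold variance.

## Evaluation

Per image the suite reports Dice, IoU (= Dice/(2−Dice)), full-frame pixel
accuracy, and the modified Hausdorff distance — the maximum of the two
directed mean-of-minimum Euclidean distances between boundary point sets.
Boundaries are mask pixels with a background 4-neighbour, with the image
border counting as background (the reference protocol does not define its
boundary extraction; this inner-boundary convention is ours). An
empty-vs-empty mask pair scores Dice = IoU = accuracy = 1 with MHD skipped;
empty-vs-nonempty scores 0 with MHD reported as NA and a warning. Areas
are pixel counts times squared pixel spacing (px² at the default spacing
1; mm² when calibrated); `bland_altman()` gives the bias, 1.96-SD limits
of agreement and absolute percentage errors of paired areas, and
`paired_ttest_bonferroni()` corrects paired two-sided t-tests for a family
of comparisons, returning 1 for identical inputs and NA (with a warning)
for degenerate constant nonzero differences.

## The phantom generator

Clinical carotid data are private, so the package ships a seeded phantom
generator that emulates the image structure the method assumes: a
longitudinal-view vessel — a dark lumen band between two bright wall
layers over mid-grey background tissue — with elliptical plaques attached
to the near or far wall and protruding into the lumen at an intensity
between lumen and wall; optionally a vertical low-intensity acoustic
shadow column and a bright horizontal artifact streak; and multiplicative
unit-mean gamma speckle (shape 4 by default, i.e. a coefficient of
variation of 0.5 — strong but realistic for envelope-detected ultrasound),
clipped to [0, 1]. Plaque masks are intersected with the vessel band at
construction, so the CBV subset invariant holds exhaustively. The default
canvas is 128×128 for desk-scale work; the 512×320 clinical working size
is supported through the parameters.

What the phantom does *not* emulate: point-spread-function-correlated
speckle, intima–media layering, curved or oblique vessels, heterogeneous
plaque composition, depth-dependent attenuation and probe-specific
artifacts. Passing phantom tests therefore demonstrates that the
architecture, augmentation, optimisation and evaluation machinery are
correct and that the network can learn this class of geometry from few
images — not clinical-grade performance; the headline clinical metrics of
the original protocol are not reproducible without its private data.

## Numerical choices

* Batch normalisation uses biased batch variance with ε = 1e-5; running
  statistics (momentum 0.1) are used at inference.
* Bilinear ×2 upsampling uses half-pixel centres with clamped borders; its
  backward pass is the exact adjoint (verified in tests).
* Max pooling breaks ties toward the first-scanned element; the 7×7 stem
  and 3×3/2 pool follow the stock ResNet-50 hyperparameters.
* The softmax head weights are scaled by 0.1 at initialisation so training
  starts near-uniform; all other convolutions are He-normal.
* All computation is double precision on CPU; with fixed seeds, training
  is bitwise reproducible (asserted in the tests).
* The convolution core is im2col + BLAS gemm in C++ (RcppArmadillo), with
  analytic backward passes checked against central finite differences.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes a single CPU handles in
minutes, chosen once as the package's desk-scale protocol: structural
tests run a 32×64 phantom; the overfitting smoke test trains on two 64×64
phantoms for 200 steps (learning rate 1e-3, the value we use for all
short runs — at 1e-4 a 200-step run barely moves); the scaled-down
cross-validation runs 2 folds over twenty 128×128 phantoms for 2 epochs.
With those sizes the held-out Dice on phantoms is around 0.9, far above
the all-background predictor's 0; the full 10-fold, 100-epoch, 40-image
protocol is available unchanged through `run_crossval()` defaults.

## Known limitations

* No GPU path; the 512×320, 100-epoch clinical protocol is hours of CPU
  time rather than minutes of GPU time.
* Pretrained encoder weights must be supplied externally; no downloader is
  included, and all shipped results use random initialisation.
* The HAC fusion wiring (concatenation + 1×1) is one reasonable reading of
  an under-specified design; alternatives (summation, per-branch gating)
  are not implemented.
* Accuracy is computed over the full frame, which inflates it when the
  plaque is small relative to the image — matching how such protocols are
  usually reported, but worth remembering when comparing numbers.
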