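# plaqueseg

Automated segmentation of carotid artery plaques in B-mode ultrasound
images, for vascular-imaging researchers who need a fully reproducible,
CPU-only reference implementation of the HRU-Net recipe: encoder transfer
learning, hybrid atrous convolutions, vessel-constrained augmentation and
a complete evaluation suite.

Plaques protrude from the artery wall into the lumen; on ultrasound their
boundaries are blurred by speckle, acoustic shadows and artifacts, and
labelled clinical images are scarce. The package addresses the
small-sample regime with three coupled ideas:

* **HRU-Net** — a ResNet-50 encoder (bottleneck stages of 3/4/6/3 blocks,
  `y = F(x, W) + x`) whose stage outputs are reduced by 1×1 convolutions
  to 32/64/96/128/128 channels, under a U-Net-style decoder with skip
  concatenation and a per-pixel 2-class softmax. Pretrained encoder
  weights can be loaded for fine-tuning (`load_pretrained_encoder()`).
* **HAC modules** — hybrid atrous convolutions on the deep semantic
  layers: parallel dilated 3×3 convolutions at rates 1, 2, 3, 5 beside a
  cascaded rate-1→2→3 chain whose receptive field is
  `RF = 1 + Σ rᵢ(Kᵢ−1) = 13`; branches fuse by concatenation + 1×1
  convolution, so the block is a drop-in at any layer (`build_hac()`,
  `hac_placement_for_count()` for the 0–6 module ablation).
* **Training-only augmentation** — six geometric variants per image
  (identity, flips, 180°, ±30°) plus the cropped-blood-vessel pair
  (image × vessel mask and its vertical flip), applied identically to
  labels: 40 originals → 320 training pairs. The loss is a class-weighted
  Dice loss `Σₑ Cₑ(1 − 2ΣLₑSₑ/(ΣLₑ+ΣSₑ))` with C₀ = C₁ = 0.5, optimised
  by Adam (lr 1e-4, β₁ 0.9, β₂ 0.999, ε 1e-8) under 10-fold
  cross-validation; new images are predicted by averaging the k fold
  models' softmax maps.

Evaluation covers Dice, IoU, full-frame accuracy, the modified Hausdorff
distance between mask boundaries, plaque-area error, Bland–Altman
agreement and Bonferroni-corrected paired t-tests.

Since clinical carotid data are private, the package ships a seeded
phantom generator (`generate_phantom()`): a longitudinal vessel with dark
lumen between bright walls, wall-attached elliptical plaques,
multiplicative unit-mean gamma speckle, optional acoustic shadow and
artifact streak. The convolutional core (dilated convolution, batch norm,
pooling, bilinear upsampling, Adam, reverse-mode tape) is implemented in
C++ via RcppArmadillo and verified against finite differences in the
tests.

## Worked example

A desk-scale experiment — eight 64×64 phantoms, 2-fold cross-validation,
4 epochs — runs in about two minutes on one CPU:

```r
library(plaqueseg)

cfg <- run_config(
  phantom = phantom_params(height = 64L, width = 64L,
                           lumen_half_thickness = 12L, wall_thickness = 5L,
                           plaque_axis_range = c(5L, 11L)),
  train = train_config(lr = 1e-3, epochs = 4L, batch_size = 4L,
                       seed = 1, folds = 2L),
  model = model_config(in_height = 64L, in_width = 64L, seed = 1),
  n_images = 8L)
cv <- run_crossval(cfg)
print(cv$summary, digits = 3)
#>      metric   mean      sd
#> 1      dice  0.841  0.0383
#> 2       iou  0.727  0.0566
#> 3       acc  0.968  0.0119
#> 4       mhd  1.601  0.8721
#> 5 delta_tpa 93.750 63.7736
```

Each held-out phantom is evaluated un-augmented by its fold's model; the
pooled mean ± SD says the network recovers plaques with Dice 0.84 and
boundary error of 1.6 pixels (MHD) after minutes of training, while
`delta_tpa` (in px² here; mm² once a pixel spacing is supplied) shows it
still over-segments small plaques at this training budget. Softmax-mean
ensembling of the fold models generalises to unseen phantoms:

```r
img <- generate_phantom(phantom_params(height = 64L, width = 64L,
                                       lumen_half_thickness = 12L,
                                       wall_thickness = 5L,
                                       plaque_axis_range = c(5L, 11L),
                                       seed = 99))
probs <- ensemble_predict(cv$models, img$image)
dice(img$plaque_mask, prob_to_mask(probs))
#> 0.898
receptive_field(c(3, 3, 3), c(1, 2, 3))
#> 13
```

The defaults of `run_config()` reproduce the full protocol (40 images,
10 folds, 100 epochs, lr 1e-4) unchanged; a command-line front end with
`phantom`, `augment`, `crossval`, `ablate`, `evaluate` and `predict`
subcommands lives at `inst/cli/plaqueseg.R`.

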