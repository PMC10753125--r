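# mamseg

Multiclass segmentation of mammograms into **background (0), breast (1)
and pectoral muscle (2)**, for both standard screening views (CC and MLO)
and both image kinds ("for presentation"/processed and "for
processing"/raw). The pectoral muscle must be excluded from any automated
breast-tissue analysis — density estimation, CAD features — or it biases
the result; in CC views the muscle is usually absent and, when present,
small, so detecting it at all is part of the problem.

The package implements the whole pipeline in R (with an
Rcpp/RcppArmadillo numerical core) and ships a synthetic phantom
generator so everything runs end to end at desk scale:

* **image_io** — PNG + manifest I/O, resampling to a common pixel
  spacing, display windowing with jitter, chest-wall-left orientation.
* **mask_init** — Otsu-based mask bootstrapping: breast boundary first,
  then a second Otsu pass inside the breast for the MLO pectoral wedge.
* **augment** — joint image/mask augmentation: window jitter, flip,
  rotation, elastic deformation, crop, gamma, noise.
* **unet** — 4-scale U-Net (two 3x3 convs per block, 2x2 max pooling,
  bilinear upsampling, dropout + 1x1 conv + softmax head), written from
  scratch with a finite-difference-verified backward pass.
* **losses** — weighted cross-entropy and focal loss over the three
  classes, with `p_t,c = p_c` if `y = c` else `1 - p_c`:
  `CE = -sum_c alpha_c log p_t,c`,
  `FL = -sum_c alpha_c (1 - p_t,c)^gamma log p_t,c`.
* **trainer** — patient-level splits, Adam + early stopping (patience on
  the validation loss), the `alpha_pectoral x loss` grid search, and the
  raw-inclusion and leave-one-style-out experiment harnesses.
* **evaluate** — per-class dice `DICE(c) = 2|pred_c ∩ truth_c| /
  (|pred_c| + |truth_c|)`, truth-pixel-weighted overall dice, any-pixel
  pectoral FP/FN detection rules, t-tests, ANOVA + Tukey HSD.
* **phantom** — parametric CC/MLO breast phantoms with exact masks,
  paired raw/processed renderings and configurable vendor styles
  (pectoral present in 99% of MLO / 28% of CC draws; area fractions
  N(0.21, 0.14) and N(0.04, 0.03) of the breast region).

## Worked example

Train a reduced U-Net on phantoms and evaluate it:

```r
library(mamseg)
set.seed(1)
cfg <- phantom_config(image_size = 64)
phantoms <- lapply(1:60, function(i)
  generate_phantom(cfg, patient_id = sprintf("p%02d", i)))
recs <- lapply(phantoms, function(s) {
  o <- orient_chest_wall_left(s$processed, s$truth)
  list(image = o$image, mask = o$mask, truth = o$mask)
})

fit <- train_model(
  build_unet(unet_config(depth = 2, base_filters = 8)),
  recs[1:40], recs[41:50],
  train_config(loss = loss_config("cross_entropy", alpha_pectoral = 2),
               lr = 1e-3, batch_size = 1, max_epochs = 15, patience = 10,
               seed = 7, policy = scale_policy(augmentation_policy(), 64)))
tail(fit$history, 1)
#>    epoch train_loss  val_loss val_breast_dice val_pectoral_dice val_overall_dice
#> 15    15  0.5845326 0.2085321       0.9370224         0.5081425        0.9332858

evaluate_dataset(fit$model, recs[51:60])$summary
#>   stratum  n breast_dice_mean breast_dice_sd pectoral_n pectoral_dice_mean
#> 1      CC  4        0.9776783     0.01102763          2          0.0000000
#> 2     MLO  6        0.9312423     0.04589636          6          0.9027890
#> 3     all 10        0.9498167     0.04225891          8          0.6770917
#>   pectoral_dice_sd overall_dice_mean overall_dice_sd
#> 1       0.00000000         0.9596000      0.03180057
#> 2       0.09264872         0.9344416      0.03735796
#> 3       0.42518246         0.9445050      0.03579413
```

Reading the summary: the ten held-out phantoms score a mean overall dice
of 0.944. The six MLO images get their pectoral wedge segmented well
(dice 0.90); the two CC images with a pectoral muscle are missed
entirely (dice 0) — the pectoral class in CC views is tiny and often
absent, which is exactly why it is the hard part of this problem and why
the class is up-weighted. At the larger phantom scale used by the
acceptance checks (128x128, 200 training images, depth-3/8-filter
network) the held-out overall dice reaches ~0.99 and the MLO pectoral
dice ~0.99.

The same pipeline is scriptable from a shell via `exec/mamseg`
(`simulate`, `init-masks`, `train`, `predict`, `evaluate`).

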