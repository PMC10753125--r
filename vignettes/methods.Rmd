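---
title: "Segmenting breast and pectoral muscle in mammograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting breast and pectoral muscle in mammograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mamseg)
```

## The problem

Automated analysis of digital mammograms (density estimation,
computer-aided detection) needs a prior segmentation of each image into
background, breast tissue and — when depicted — pectoral muscle, because
muscle pixels bias any measure computed over "the breast". Two practical
complications shape the design here:

* **Views.** The MLO (mediolateral oblique) projection almost always shows
  the pectoral muscle as a wedge at the chest-wall corner, and it is large
  (about a fifth of the breast area on average). The CC (cranio-caudal)
  projection shows it in only about a quarter of images, and then small
  (a few percent of the breast area). A single model must handle both,
  which creates a strong class imbalance for the pectoral class.
* **Vendors and image kinds.** "For presentation" (processed) images look
  different across manufacturers — gray level, contrast, texture — and
  "for processing" (raw) images have nearly inverted, compressed contrast.
  A segmentation model should generalize across these appearances.

`mamseg` implements the full pipeline as a tested R package: mask
initialization, augmentation, network, losses, training with
hyperparameter selection, evaluation with detection statistics, plus a
synthetic phantom generator so every stage can be exercised end to end at
desk scale without access to clinical data.

## Segmentation model

The network is a standard four-scale U-Net operating on a single-channel
intensity grid in [0, 1]:

* Encoder: `depth` (default 4) blocks of two 3x3 same-padded convolutions
  with ReLU, then 2x2 max pooling; filters start at `base_filters`
  (default 64) and double at each scale.
* Decoder: bilinear 2x upsampling, a 1x1 convolution halving the
  channels, concatenation with the encoder skip, then two 3x3
  convolutions with ReLU.
* Head: dropout (probability 0.5, training only), a 1x1 convolution to 3
  channels, softmax per pixel.

Weights are Kaiming-uniform initialized (bound `sqrt(6/fan_in)`, giving
variance `2/fan_in`); biases start at zero. No batch normalization is
used. Same-padding keeps the output grid equal to the input grid, which
the pixel-level dice evaluation requires; inputs whose side is not a
multiple of `2^depth` are zero-padded and the output cropped back.

Because no deep-learning framework is available to R in this environment,
the numerical core (im2col convolution forward/backward, max pooling,
bilinear upsampling, warping) is implemented in C++ via Rcpp/
RcppArmadillo, with the layer graph, softmax, losses and the Adam
optimizer in R. The backward pass is verified against central finite
differences in the test suite (relative error ~1e-7).

## Losses

Training uses per-pixel multi-class losses with class weights
`alpha = c(1, 1, alpha_pectoral)`. With `p_c` the predicted probability
of class `c` and `y` the true label, define `p_t,c = p_c` if `y = c` and
`1 - p_c` otherwise. Then

* weighted cross-entropy: `-sum_c alpha_c * log(p_t,c)`,
* focal loss: `-sum_c alpha_c * (1 - p_t,c)^gamma * log(p_t,c)`.

Both are averaged over pixels so the magnitude does not depend on the
crop size, and logs are clamped at 1e-12. Two details deserve note:

* The `p_t` convention above includes `1 - p_c` terms for the non-true
  classes (a per-class, binary-style formulation) rather than the more
  common true-class-only form. It is implemented exactly as defined;
  the brute-force oracles in the tests use the same definition.
* The focal loss reduces to the weighted cross-entropy at `gamma = 0`
  (algebraically, `(1-p)^0 = 1`), and the equivalence test runs at
  `gamma = 0`. The focal default is `gamma = 2`.

Increasing `alpha_pectoral` strictly increases the loss whenever
pectoral-truth pixels are imperfectly predicted; the grid search explores
`alpha_pectoral` in {1, 1.5, 2, 2.5} for both losses and selects the
candidate with the highest mean validation pectoral dice (computed only
over validation images whose truth contains the class), breaking ties by
overall dice and then by the smaller alpha.

## Augmentation

Each training sample passes once through, in order: display-window (LUT)
jitter, random horizontal flip, random rotation, elastic deformation,
random crop, random gamma, additive Gaussian noise. Geometric steps warp
image and mask with the identical map (bilinear for intensities,
nearest-neighbor for labels, zero/background fill); intensity steps touch
the image only. Defaults:

| step | parameter | default |
|---|---|---|
| LUT jitter | center/width relative jitter | 5% |
| flip | probability | 0.5 |
| rotation | angle range | +/-5 degrees |
| elastic | alpha, sigma, alpha_affine | 1, 100, 20 px |
| crop | size, max outside | 512, 64 px |
| gamma | exponent range | (0.5, 1.5) |
| noise | sd / image range | 5% |

The elastic step follows the convention the parameter triple comes from:
uniform [-1, 1] displacement fields smoothed by a Gaussian of width
`sigma` (FFT, periodic boundary) and scaled by `alpha`, composed with a
random affine estimated from three corner points jittered by up to
`alpha_affine` pixels; the displacement and affine are combined into one
warp per call.

The pixel-based magnitudes (`sigma`, `alpha_affine`, crop geometry) are
calibrated for 512x512 crops of 400 um images. When training on smaller
grids, `scale_policy()` shrinks them proportionally; without this, a
20-pixel affine jitter on a 64-pixel phantom is a ~30% distortion that
destroys convergence (observed directly during development). Scale-free
parameters (jitter fractions, probabilities, angles, gamma, noise
fraction) are left unchanged.

Noise is applied after gamma and the result clipped to [0, 1], keeping
the network input domain fixed. Crop origins are uniform over all
positions whose window stays within the image dilated by `max_outside`
on every side; the crop is not biased toward the breast.

Out-of-bounds areas created by rotation, elastic deformation or crop
overshoot are filled, at the `augment_sample()` level, with the image's
own background level (the median of its border pixels) rather than a hard
zero; the mask fill is always the background label. For processed images
the border is near zero, so this is practically the classic zero fill —
but raw images have a *bright* unattenuated background, and zero-filled
borders labeled "background" teach the network a contradictory
appearance. In mixed raw+processed phantom training, zero fill capped the
processed-image dice at roughly 0.88 while background fill restores both
domains to ~0.97; the exported individual operations keep a `fill = 0`
default.

## Mask initialization

Ground-truth masks for real data are bootstrapped in two Otsu steps
before manual correction; the package reproduces the automated part:

1. `init_breast_mask()`: global Otsu threshold on the windowed image;
   keep the largest connected component; fill holes. The
   largest-component + hole-fill cleanup is this package's own minimal
   stand-in for the manual correction stage, and is flagged as such.
   When the between-class variance of the best split is below 1e-3
   (intensity^2 units on [0,1] grids — essentially a flat image), the
   result is an empty mask flagged `degenerate`.
2. `init_pectoral_mask()`: for MLO views only, Otsu again over
   breast-interior intensities; among above-threshold components, the one
   reaching the left image edge within the top quarter of rows becomes
   the pectoral label. The corner rule is a design addition (no spatial
   constraint is inherent to the thresholding); without it, bright
   texture elsewhere in the breast is mislabeled. CC views pass through
   unchanged — no initialization is defined for them.

Otsu uses 256 bins over the observed range; ties in the between-class
variance go to the lower bin. The implementation is checked against an
exhaustive maximization oracle.

## Training

* Optimizer: Adam. The learning rate, batch size and epoch budget are not
  prescribed by the method itself; defaults are `lr = 1e-4`,
  `batch_size = 8`, `max_epochs = 200`, all config-exposed. The phantom
  experiments in this package use `lr = 1e-3` with single-image updates,
  which converges fastest at desk scale.
* Early stopping: training stops when the epoch-mean validation loss has
  not strictly improved its running best for `patience` (default 10)
  consecutive epochs; the returned weights are those of the best
  validation epoch. Validation uses the metadata window with no
  augmentation.
* Splits are patient-level: whole patients are assigned greedily to test
  until it holds the requested image count, then to validation, remainder
  to train; no patient straddles splits.
* Raw inclusion: when enabled, raw images join training as independent
  samples carrying the same mask as their processed counterpart (the two
  renderings are pixel-aligned by construction).

## The phantom generator

Real multi-vendor mammogram collections cannot ship with a package, so a
parametric phantom stands in. It is deliberately non-anatomical — geometry
primitives chosen to exercise every pipeline stage:

* Breast: half-ellipse attached to the left (chest-wall) edge, randomized
  semi-axes, a smooth low-frequency boundary wiggle, and a vertical shear
  for MLO views. The ellipse's chest-wall extent is kept below the top
  quarter of rows, so only a pectoral wedge can occupy the corner region
  the mask initializer searches.
* Pectoral: present with probability 0.99 (MLO) / 0.28 (CC); its area as
  a fraction of the breast region is drawn from N(0.21, 0.14) (MLO) or
  N(0.04, 0.03) (CC), redrawn while outside (0.01, 0.9) and falling back
  to the mean after 100 rejections. MLO uses a corner wedge whose scale
  is fitted by bisection on the rasterized pixel counts, making the truth
  mask exact by construction (relative area error below 2%); the wedge
  aspect ratio is capped so it always meets the ellipse at the chest
  wall, keeping the breast region connected. CC uses a small chest-wall
  crescent fitted the same way.
* Appearance: tissue and muscle get smooth textured intensities (muscle
  brighter), then a vendor style maps them to the processed rendering
  (`background + gain * x^gamma + noise`, optional film label/edge
  artifacts placed outside the breast); the raw rendering inverts the
  contrast (bright unattenuated background, darker tissue, compressed
  range), so a model trained only on processed phantoms fails on raw
  ones — the qualitative failure mode the raw-inclusion experiment
  measures. Laterality is drawn 50/50 and right-sided images stored
  mirrored.

These prevalence/size defaults are the study conditions for all phantom
experiments and are not tuned per test. What the phantom does **not**
emulate: anatomical tissue structure, lesions and calcifications, detector
physics, vendor-specific texture signatures, or burned-in annotations.
Passing the end-to-end tests therefore shows the pipeline is implemented
coherently — data flow, losses, optimization, evaluation — not that the
trained weights would transfer to clinical images.

## Numerical and design choices

* Resampling: target dimension `round(dim * spacing/target)` with halves
  away from zero; bilinear for intensities, nearest-neighbor for labels.
  A single warping backend (C++) serves resampling, rotation and elastic
  deformation.
* Windowing: only linear center/width ramps are implemented; `jitter = 0`
  reproduces the metadata window exactly (the test-time setting). Raw
  images bypass windowing and are min-max normalized (optional log
  transform, off by default).
* Orientation: all processing happens chest-wall-left; laterality "R"
  images are mirrored (predictions can be mirrored back), unknown
  laterality is inferred from which half holds more foreground.
* Argmax decoding breaks ties toward the lower class index.
* Dice for a class absent from the truth is undefined and excluded from
  averages (never scored 0); false-positive pressure is reported through
  the any-pixel FP rule and the 1%-of-breast-area FP size flag instead.
  The overall dice weights breast and pectoral dice by their truth pixel
  counts.
* Group comparisons: plain Student t-tests by default (Welch available),
  one-way ANOVA with Tukey HSD, Bonferroni thresholds `alpha/k` for the
  leave-one-style-out family; sample (n-1) standard deviations in
  summaries.

## Problem sizes used by the tests and the acceptance script

End-to-end phantom training runs at 128x128 with a depth-3, 8-filter
U-Net on 200 training phantoms (two vendor styles), which converges in
under ten epochs of single-image Adam updates; the raw-inclusion and
leave-one-style-out harnesses run at 64x64 with a depth-2 network and a
few dozen phantoms per arm (the mixed raw+processed model is the slowest
learner and gets the largest epoch budget). These sizes are the package's choice of
desk-scale study conditions: large enough for stable dice ceilings
(~0.97 overall on phantoms), small enough to rerun routinely.

## Known limitations

* DICOM reading is not implemented (no R DICOM reader in the dependency
  set); input is 8/16-bit PNG plus a manifest CSV.
* `write_image()` stores 8-bit PNGs, so image (not mask) round trips
  quantize intensities.
* The Otsu pectoral initialization degrades for very small or
  low-contrast wedges — the motivation for the manual-correction stage it
  bootstraps, which is out of scope here.
* Training is single-threaded CPU; the architecture defaults
  (depth 4, 64 filters) are far slower than the reduced phantom
  configurations and are intended for real-data scale.
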