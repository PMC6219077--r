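---
title: "Methods: patch-based CNN probability maps for retinal lesion segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based CNN probability maps for retinal lesion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Diabetic retinopathy is diagnosed from color fundus photographs by locating
three kinds of pathological sign: **exudates** (bright yellowish lipid
deposits), **hemorrhages** (larger dark red bleeds) and **microaneurysms**
(tiny dark red dots, the earliest sign). `fundusdr` implements a complete
patch-based convolutional pipeline that detects and segments all three signs
simultaneously, with mutually exclusive output masks.

The pipeline has two phases.

**Patch phase.** Images are contrast-enhanced with the Gaussian-difference
transform

$$I_{CE}(x,y) = \alpha\, I(x,y) + \beta\, (G_\sigma * I)(x,y) + \mu,$$

with $\alpha = 4$, $\beta = -4$, $\sigma = 10$ px (at the 1500-px reference
width) and $\mu = 128$. Because $\alpha = -\beta$ and the kernel sums to one,
flat regions map exactly to the mid-gray $\mu$ and local structure is
amplified four-fold: the transform is a scaled high-pass filter that
equalizes illumination and makes small dark dots and bright deposits stand
out from the retinal background. Enhanced images are tiled into
non-overlapping $S \times S$ patches ($S = 50$ at reference resolution),
labeled from ground-truth masks (a patch gets a sign's label when that sign
covers at least 10 % of it; larger overlap wins ties, then the fixed
priority exudate > hemorrhage > microaneurysm), split 70/15/15 stratified by
class, and used to train a four-class classifier:

4 × [conv 16@3×3 → ReLU → maxpool 2×2 → normalization] → FC 256 → ReLU →
dropout 0.5 → FC 4 → softmax.

Training minimizes the mean cross entropy
$L_c = -\tfrac1{|C|}\sum_i \ln p(D^i \mid C^i)$ by mini-batch SGD with the
literal update rule

$$\theta^{(p+1)} = \theta^{(p)} - \gamma\,\partial L_c/\partial\theta
  + \vartheta\, \Delta\theta^{(p)} - a\,\gamma\,\theta^{(p)},$$

i.e. classical momentum ($\vartheta = 0.9$) plus weight decay
($a = 5\times10^{-4}$), batch size 128, and a step-down learning-rate policy
($\gamma \leftarrow 0.1\,\gamma$ every 33 epochs). The training split (only)
is augmented with the 8 dihedral variants of each patch.

**Image phase.** A trained classifier is slid across the whole image: the
$S\times S$ window centered on each pixel is classified and the softmax
scores are written at that pixel, giving three per-sign probability maps
$P_E, P_H, P_M$ (plus implicit background). Each map is binarized at a
threshold chosen on *held-out* images by maximizing Youden's
$J = \text{sensitivity} + \text{specificity} - 1$ over all candidate cuts;
overlapping claims are resolved by probability ranking (exact ties by the
fixed sign priority); each sign's mask is then cleaned by morphological
closing (5×5), opening (5×5) and erosion (4×4) followed by removal of
8-connected components smaller than $S^2/4$ pixels.

The decisive design element is that segmentation consumes the *soft*
probability maps, not the classifier's argmax: a sign class that is rarely
the argmax winner can still be recovered cleanly, because its probability is
consistently higher over true lesions than over background and the
ROC-optimal threshold finds that separation.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha`, `beta`, `mu` | 4, −4, 128 | – / gray | reference enhancement constants; `alpha = -beta` makes flats map to `mu` |
| `sigma` | 10 at 1500-px width | px | enhancement scale; scaled with image width |
| `patch_size` | 50 at 1500-px width | px | set by the smallest sign at reference resolution |
| `label_rule_min_overlap` | 0.10 | fraction | reproducible surrogate for manual patch curation |
| `split_fractions` | 0.70/0.15/0.15 | – | standard train/validation/test proportions |
| `feature_maps`, `fc_units`, `dropout_rate` | 16, 256, 0.5 | – | reference architecture |
| `learning_rate`, `momentum`, `weight_decay` | 0.01, 0.9, 5e-4 | – | reference optimizer settings (decay: conventional value) |
| `lr_gamma`, `lr_step`, `max_epochs` | 0.1, 33, 43 | – / epochs | reference step-down policy and saturation epoch |
| `stride` (mapping) | 1 (`run_pipeline`: 2) | px | per-pixel definition; a small stride with bilinear fill is indistinguishable on smooth maps and far cheaper |
| morphology kernels | 5, 5, 4 | px | reference cleanup sizes |
| area rule | `S^2/4` | px | reference minimum lesion area |

## Resolution scaling

All of the method's length parameters refer to 1500-px-wide images. The package's
rule, applied consistently by `run_pipeline()`, is to scale *every*
length-valued parameter by `width/1500` (`scale_to_width()`): the Gaussian
scale, the patch side, the morphology kernels and the (quadratic) area rule.
At the default 300-px synthetic resolution this gives `sigma = 2` px and a
patch side of 10 px, which is below the 16-px minimum that four 2×2 pooling
stages admit, so the patch side is floored at 16 px and the morphology
kernels become 2/2/1 with a minimum area of `16^2/4 = 64` px. Without this
scaling a 50-px window cannot localize lesions smaller than itself, and the
625-px area rule would delete every hemorrhage and microaneurysm at 300-px
scale — the reference lengths only make sense at the resolution they were
defined for.

## The synthetic fixture

Clinical datasets are neither redistributable nor desk-scale, so the package
ships a seeded generator (`simulate_fundus()`) producing fundus-like images:
a reddish-orange disc (circular field of view, mild vignetting) on black,
smooth dark vessel-like curves, and three lesion classes — bright soft-edged
blobs (radius 8–14 px, +80 gray), larger dark red blobs (8–13 px, −70, drawn
as rotated ellipses), tiny dark red dots (3–5 px, −80) — placed by rejection
sampling with ≥ 2 px clearance, masks recorded exactly where intensity was
modified, hence pairwise disjoint by construction. Pixel noise is Gaussian
with sd 2 gray levels: the enhancement multiplies high-frequency noise by
`alpha = 4`, and sd 2 keeps the enhanced signal-to-noise ratio in the range
of real fundus cameras. Defaults per image: 3 exudates, 2 hemorrhages,
5 microaneurysms, 4 vessels at 300 px.

What the fixture does *not* model: optic disc, drusen, laser scars,
illumination gradients beyond vignetting, camera artifacts, or the
photometric statistics of any clinical database. Passing the end-to-end test
therefore demonstrates that the pipeline's machinery — enhancement, patch
learning, probability mapping, threshold fitting, post-processing — recovers
planted signal under controlled conditions; it says nothing about clinical
accuracy on real images, which only evaluation on expert-annotated fundus
databases can establish.

## Numerical and calibration choices

* **Gaussian kernel**: truncated at 4σ per side and renormalized to unit
  sum, so the constant-image identity `f(c) = mu` is exact, not approximate;
  reflect padding avoids dark rims at the field-of-view boundary.
* **Window extraction** for mapping reflect-pads by `floor(S/2)` so every
  pixel has a full centered window (for even `S` the center sits at offset
  `floor(S/2)`).
* **Convolution layers** use zero same-padding; pooling floors odd sides
  (50 → 25 → 12 → 6 → 3). The normalization layer is local response
  normalization across channels (n = 5, α = 1e-4, β = 0.75, k = 1 — the
  conventional settings of the era); batch normalization is available via
  `network_config(norm = "batch")` since the normalization type admits
  either reading.
* **Forward/backward passes** are im2col + BLAS GEMM with compiled kernels;
  gradients are validated against central finite differences in the test
  suite (relative error < 1e-4 at randomized O(1) parameters).
* **Conditioning at desk scale**: the reference zero-mean Gaussian init
  (sd 0.01) is the `network_config()` default, but with 16-px inputs and
  [0,1]-scaled intensities it leaves activations of order 1e-6 after four
  blocks and training stalls at the class prior. The desk-scale
  `run_pipeline()` therefore initializes at sd 0.1 and normalizes with batch
  normalization rather than LRN: with LRN the small network never learns to
  tell a window centered on a hemorrhage (dark core plus the bright
  high-pass halo the enhancement creates around it) from an exudate, and
  overlap resolution then hands hemorrhage pixels to the exudate map;
  batch-normalized training resolves that boundary cleanly. The run's
  learning rate is 0.03 with a step-down at epoch 12, and its epoch count
  (20) was chosen by watching validation accuracy saturate on fixture data —
  the same procedure the reference training used to pick its 43 epochs.
* **Threshold selection** sweeps every distinct score as a candidate cut,
  maximizing Youden's J, ties toward the higher threshold; the
  closest-to-(0,1) criterion is available behind a switch. Thresholds are
  fitted on the held-out `threshold` role of the image set, never on test
  images. Degenerate (single-valued) score vectors warn.
* **Exclusivity after morphology**: closing can re-join pixels claimed by
  different signs; `segment_image()` re-resolves such conflicts by
  probability and re-applies the area rule, so disjointness *and* the
  minimum-area guarantee both hold in the final masks.
* **Even structuring elements**: the 4×4 erosion uses a top-left-of-center
  origin (offset `floor(k/2)` per axis), implemented by exact Minkowski
  shift-combination; pixels beyond the border count as background.
* **Undefined metrics** (0/0, e.g. PPV with no positive predictions) are
  reported as `NA` with a flag, never silently zeroed. Pixel-level metrics
  are restricted to the field of view, since black corners would inflate
  true negatives.

## Problem sizes

The default `run_pipeline()` study uses 20 images of 300 px (12 train /
4 threshold / 4 test), 16-px patches (about 3.9k per training set before
8-fold augmentation), 20 training epochs at batch 128, and probability maps
at stride 2 with bilinear fill. These sizes were chosen so that a complete
run, including training, finishes in minutes on a single CPU core while
every stage still operates in its intended regime.

## Known limitations

* Overlapping hemorrhages and microaneurysms cannot be distinguished within
  a single connected region — a stated limitation of the method itself.
* The sliding-window classifier sees lesions smaller than its window at any
  position, so probability maps bloom beyond small lesion borders by up to
  half a window; the ROC threshold and erosion shrink but do not eliminate
  this, which bounds attainable boundary precision (Dice) for the smallest
  signs.
* Per-pixel mapping at stride 1 on full-resolution clinical images is
  computationally expensive by design (no fully-convolutional shortcut is
  provided, matching the method as described).
* The training loop is single-threaded CPU code; it is meant for desk-scale
  experiments, not for training on clinical corpora.

## A minimal session

```{r}
library(fundusdr)

res <- run_pipeline(out_dir = "rundir", seed = 1)
res$pixel_metrics       # per-sign pixel-level Table-2 metrics on test images
res$thresholds          # fitted Youden thresholds per sign
autoplot(res$model)     # training curves
autoplot(res$segmentations[[1]])
```
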