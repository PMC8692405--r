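---
title: "Weakly-supervised lesion classification and CAM localization on ultrasound phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly-supervised lesion classification and CAM localization on ultrasound phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(uscam)
```

## The question

Can a convolutional classifier trained from *image-level* labels alone
(benign vs malignant) both diagnose breast-ultrasound lesions and *localize*
them — without ever seeing a lesion outline? `uscam` implements this
weakly-supervised design end to end and compares it against fully-supervised
alternatives that classify a region-of-interest (ROI) crop defined by a
lesion mask, either "manual" (ground truth) or "automated" (U-Net
segmentation). Because the original clinical images are private, the package
ships a seeded B-mode phantom generator that reproduces the *statistical
structure* of the study: two classes with distinct morphology, two
validation splits, and a scanner-profile domain shift for the external
split.

## The model

The classifier is a small convolutional backbone whose final layer produces
$K$ feature maps $f_k$. A global-average-pooling (GAP) head collapses each
map into a feature score

$$F_k = \sum_{i,j} f_k(i,j),$$

a bias-free linear layer produces class scores

$$S_c = \sum_k w_{k,c} F_k,$$

softmax yields class probabilities $p_c$, and the probability of malignancy
(POM) is the malignant-class probability. The class activation map

$$M_c(i,j) = \sum_k w_{k,c} f_k(i,j)$$

is min–max scaled to $M'_c$, bilinearly upsampled to the input resolution,
and binarized at $M'_c \ge 0.3$ (inclusive). Localization is scored correct
when the binary region overlaps the ground-truth mask in at least one pixel.
Because the head has no bias, the CAM decomposes the class score exactly:
summing $M_c$ over pixels reproduces $S_c$, and the package asserts this
identity to $10^{-4}$.

Two readings of the GAP step circulate: the prose ("averages each feature
map") and the explicit sum formula. They differ only by the constant factor
$h \cdot w$, absorbable into $W$; `global_average_pool()` implements the sum
by default with `pool = "mean"` available. Similarly, the number of feature
maps is sometimes described as equal to the number of classes; the package
implements the standard CAM formulation with configurable $K \ge N_c$
(setting $K = N_c$ recovers the literal reading).

## Architecture and training choices

No deep-learning framework is involved: convolution forward/backward passes
are im2col + BLAS matrix products in C++, with the training loop (Adam,
cross-entropy + $\lambda \|w\|^2$, BCE + soft-Dice for the U-Net) in R.
Gradients of every layer are verified against finite differences in the test
suite.

The desk-scale backbone ("tiny") is four 3×3 stride-2 conv blocks with ReLU,
channels 8–16–32–32, at 128×128 input. Design choices that mattered, found
during development and fixed before the evaluation runs:

- **Conv biases and input centering.** The classification *head* is
  bias-free (that is what makes CAM an exact score decomposition), but the
  backbone's conv layers carry per-channel biases, and the input is centered
  by subtracting 0.5. Without these, a positively-homogeneous ReLU net on
  all-positive inputs cannot threshold on absolute echogenicity — precisely
  the cue that distinguishes a hypoechoic lesion — and training stalls near
  chance.
- **Head initialization scale.** All weights are He-initialized
  ($\mathcal{N}(0, 2/\mathrm{fan\_in})$). Under sum-GAP the feature scores
  carry an extra factor of the pooled area ($8 \times 8 = 64$), so the head
  init is divided by that area to keep initial logits $O(1)$; this is
  exactly He initialization with respect to mean-pooled features and is
  absorbable into $W$.
- **Optimizer.** Adam with $\beta = 0.9$, $\beta_2 = 0.999$, batch 64, L2
  regularization — the study's printed recipe. The learning rate and weight
  decay used by the default study configuration ($3\times10^{-3}$,
  $10^{-3}$) were selected by tuning-set AUC, the study's own grid-search
  procedure (`grid_search()` implements the exhaustive search with
  lower-$\lambda$-then-lower-$\eta$ tie-breaking and whole-set retraining).
  The printed default $\eta = 10^{-3}$ remains `training_config()`'s
  default.
- **Snapshot selection.** Epoch count is not stated in the original recipe;
  training runs a fixed number of epochs (40 in the default study, where
  the tuning AUC was still improving at 30) and returns the
  best-tuning-AUC snapshot.
- **U-Net.** Depth 3 (two stride-2 encoders, bottleneck, nearest-neighbour
  ×2 upsampling with skip concatenation), base 8 channels, BCE + soft-Dice
  loss, the same Adam constants, 10 epochs over 200 training images. Its
  capacity was chosen for the desk-scale budget; what it can and cannot
  segment on the default phantom mix is discussed below.

## The phantom generator

Each image is multiplicative speckle over a horizontally banded
echogenicity field, Gaussian-blurred, min–max normalized, then gamma/gain
adjusted. `speckle_scale` multiplies the speckle's *relative* fluctuation
(coefficient of variation; 1 = fully developed Rayleigh speckle, CV 0.52).
It is deliberately defined relative to the local mean: an absolute
multiplicative scale would cancel under per-image min–max normalization and
the machine-profile domain shift would be undetectable.

Lesions are hypoechoic regions composited into the background with a linear
edge ramp (`margin_sharpness`, capped at half the semi-minor axis so small
lesions still reach full contrast) and an optional soft-edged posterior
column (enhancement or shadowing). Class archetypes follow the standard
sonographic descriptors:

| parameter | benign | malignant |
|---|---|---|
| shape | ellipse, wider than tall (aspect 0.5–0.85) | star-shaped, 4–12 spicules, amplitude 0.15–0.40 |
| orientation | near-horizontal (±15°) | any |
| margin ramp | 3–6 px (circumscribed) | 0.8–2 px (sharp/angular) |
| echogenicity offset | −0.65 … −0.35 | −0.80 … −0.50 |
| posterior effect | 0 or enhancement (+0.2 … +0.5) | 0 or shadowing (−0.6 … −0.2) |
| diameter | 10–50 % of image width | same |

The echogenicity ranges overlap on purpose: mean darkness alone cannot
separate the classes (a 16×16 logistic baseline reaches only ~0.76 AUC), so
the classifier must exploit morphology. The ranges were calibrated once so
that the default study meets the design's stated learnability property (a
default classifier reaches AUC ≥ 0.90 on internal validation) while
remaining visibly noisy — per-pixel lesion contrast-to-noise stays below 1,
as in real B-mode.

The external validation split uses a shifted machine profile (speckle CV
×1.3, gamma 1.2, +0.5 px blur): enough to depress the weak arm's transfer
measurably (internal AUC 0.92–0.97 vs external 0.86–0.93 across default
seeds) without destroying it, mirroring the internal-vs-external pattern of
the clinical study.

What the phantoms do *not* emulate: physical RF/beamforming, attenuation,
spatially correlated speckle grain, tissue-composition strata
(fat/fibroglandular heterogeneity), calcifications, or multiple lesions per
image. Passing tests therefore show that the *pipeline* behaves as designed
on data with the study's structure — not that the classifier would reach
clinical performance on real images.

## Study design and defaults

`run_study()` reproduces the full design from one master seed:

- dataset: 500+500 training (100+100 flagged as the tuning subset),
  100+100 internal validation, 100+100 external validation, at 128×128
  (224×224 supported via configuration);
- arms: `weak` (whole image), `full_manual` (square ROI crop around the
  ground-truth mask — the phantom stand-in for the radiologist's
  annotation — with the fixed 30-pixel margin, margin first, then symmetric
  squaring, clipped at borders), `full_auto` (same crop driven by the
  U-Net mask; an empty predicted mask falls back to the whole image and is
  counted);
- the ROI classifier is trained once on ground-truth-mask crops and
  evaluated under both manual and automated cropping, which makes the
  oracle-segmenter identity exact: with perfect predicted masks the
  automated arm reproduces the manual arm's POMs bit for bit;
- statistics: AUC with DeLong structural-components variance and Wald 95%
  CI (clipped to [0, 1]); paired DeLong test; exact McNemar on sensitivity
  (malignant cases) and specificity (benign cases) at POM ≥ 0.5 — the
  operating point is not stated in the original report, and 0.5 is the only
  threshold-free choice for a softmax binary head; Fisher's exact test
  (conditional, point-probability two-sided) on the localization table;
  Dice for the segmenter.
- localization class policy: the predicted class's CAM by default
  (`predicted`), with `true_class` and `malignant` as alternatives — the
  original text does not say which class's map was compared for benign
  images.

Degenerate cases are decided, not left to chance: a constant CAM cannot be
min–max scaled and is returned as zeros with a flag, scoring as incorrect
localization; identical score vectors give DeLong p = 1 by convention; zero
discordant pairs give McNemar p = 1; two empty masks make Dice undefined
and raise an error.

## Problem sizes

The default study (1400 simulated images, two classifiers at 40 epochs, one
U-Net at 10 epochs, three arms × two splits) was sized to run in about ten
minutes on a single CPU; the test suite trains the full default study once
and reuses it across checks. Statistical procedures are validated against
independent oracles at small n (pair enumeration, leave-one-out jackknife,
direct binomial/hypergeometric summation, pROC) and the DeLong test's null
calibration uses 1000 simulated paired samples of n = 60.

## What the default study shows

On the default composition (seed-42 run of `analysis/02_run_study.R`), the
three arms are statistically indistinguishable on internal validation
(weak 0.97, manual-ROI 0.96, automated-ROI 0.95 AUC; DeLong p = 0.55) and
the weak arm localizes 100/100 malignant and 97/100 benign lesions — the
design's headline result: image-level labels suffice for both diagnosis
and localization on data of this structure.

The external split separates the arms: the weak and manual arms transfer
well (0.93 / 0.92 AUC) while the automated arm degrades most (0.84 AUC,
specificity 41%). The mechanism is visible in the segmenter: under the
external profile's gamma shift the U-Net, trained without augmentation,
over-segments (predicted masks 2–8× the true area; Dice drops from ~0.74
internally to ~0.35), so its crops feed the ROI classifier misleading
context. The clinical study reported the same qualitative pattern — its
automated arm's external specificity fell to 52–69% while the other arms
held — so this brittleness of segmentation-dependent pipelines under
scanner shift is a reproduced finding, not a phantom artifact. On the
default phantom mix the segmenter's internal-validation Dice (~0.74) sits
below the clinical 0.89 because the committed lesion distribution includes
small (≈13 px) low-contrast lesions whose per-pixel contrast-to-noise is
below 1; on strongly contrasting phantoms the same architecture exceeds
0.80 held-out Dice, which is what the segmenter smoke test asserts.

## Known limitations

- The tiny backbone is not VGG16/ResNet34/GoogLeNet; those published
  backbones require pretrained weights and a framework that are out of
  scope here, so multi-backbone clinical tables are not reproduced —
  only the *pattern* (weak ≈ fully supervised, internal > external).
- Speckle is spatially uncorrelated before the small point-spread blur;
  real speckle grain statistics are richer.
- The "manual" annotation arm uses the generator's ground-truth masks;
  inter-reader variability of real manual ROIs is absent.
- No data augmentation is used (none is described in the original recipe),
  which contributes to the gap between tuning and validation AUC at this
  training-set size.
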