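---
title: "Label-free lipid droplet segmentation: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free lipid droplet segmentation: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative-phase imaging (QPI) measures the optical phase delay of light
through a specimen instead of fluorescence intensity. In single-cell QPI
images of oleaginous yeast, lipid droplets (LDs) appear as bright round
regions because their refractive index exceeds that of the surrounding
cytosol, which in turn exceeds the near-zero background. The refractive
index contrast between droplets and other organelles is small, however, so
simple phase thresholding mislabels many pixels. `dropseg` frames droplet
localization as per-pixel binary semantic segmentation (lipid /
non-lipid) and provides two learned routes plus the thresholding baseline:

1. **Classical pixel classification.** Each image is min-max normalized to
   8 bits and expanded by a bank of 80 parametrized image filters into a
   per-pixel feature vector; feature vectors from all training images are
   flattened into one `n x 80` matrix and fitted by one of five backends:
   random forest (RF), gradient boosting (XGB), polynomial-kernel support
   vector machine (SVM), multilayer perceptron (MLP), or linear
   discriminant analysis (LDA).
2. **A U-Net convolutional network** trained end-to-end on padded
   256x256 (or reduced 64x64) images with binary cross-entropy.

Evaluation uses the standard six scores (accuracy, balanced accuracy,
precision, recall, Sorensen-Dice/F1, Jaccard), ROC/AUC, unshuffled k-fold
cross-validation, and training-set-size sweeps.

## The synthetic scene generator

No public single-cell QPI/mask corpus accompanies this problem, so the
package ships a generator whose scenes contain the features the
classifiers must learn: a dark homogeneous background (phase 0), one
elliptical cell of intermediate phase, and 0-6 bright circular droplets
strictly inside the cell, with additive Gaussian noise and optional
Gaussian blur. The ground-truth mask is rasterized from the drawn disks
*before* noise, so it is exact; anti-aliasing is deliberately off.

Two presets are frozen so that test properties are stable:

* `easy`: phase levels background/cell/droplet = 0/1/3, noise sd 0.1, no
  blur. High contrast; a well-trained classifier should recover droplets
  almost perfectly, which makes recovery failures diagnostic.
* `hard`: levels 0/1/1.6, noise sd 0.35, blur sd 1.0. Compresses the
  droplet-cytosol contrast toward the regime where direct thresholding
  degrades.

Default geometry at canvas 64: cell semi-axes 16-24 px with up to 8%
centre jitter, droplet radii 2-6 px (scaled with the canvas, floored at
1 px), droplets non-overlapping and wholly inside the cell ellipse.
Droplet placement is rejection-sampled with a bounded retry budget; an
impossible geometry errors rather than silently degrading.

What the generator does *not* emulate: speckle and halo artifacts of real
interferometric imaging, partial-volume effects at droplet boundaries,
multi-cell crowding, apoptotic or budding morphologies, and correlated
noise. Passing the recovery tests therefore demonstrates that the
pipelines are implemented correctly and can learn the phase-morphology cue
they are designed for; it does not certify accuracy on real microscope
data.

## The filter bank

The bank totals exactly 80 layers and always retains the untouched
normalized image as layer 1, since the raw intensity is itself
informative. The remaining families cover smoothing, edges, blobs, local
statistics and intensity ordering over a shared sigma ladder
(0.3, 0.7, 1.0, 1.6, 2.5, 3.5, 5.0, 7.5, 10.0 px):

| family | count | parameters |
|---|---|---|
| identity | 1 | - |
| Gaussian smoothing | 9 | the sigma ladder |
| difference of Gaussians | 8 | consecutive sigma pairs |
| Laplacian of Gaussian | 9 | sigma ladder |
| Sobel magnitude after Gaussian | 9 | sigma ladder |
| Gaussian gradient magnitude | 9 | sigma ladder |
| structure-tensor eigenvalues | 18 | large then small, sigma ladder |
| median filter | 9 | windows 3, 5, 7, 9, 11, 15, 19, 25, 31 |
| intensity threshold | 8 | per-image quantiles 0.1-0.8 |

Named filter families for this kind of pixel-classification pipeline are
standard, but a complete parameterization is a design choice; the bank
above covers every named family across multiple scales, is frozen as
`default80` for reproducibility, and is fully configurable (and
serializable to YAML) for users who want a different composition.

Numerical conventions: all convolutions reflect at the image edge
(mirror with edge duplication), which avoids spurious edge responses on
padded borders; Gaussian and derivative kernels are sampled at radius
3 sigma and normalized so that the response to 1, x, and x^2/2 is exactly
1 for orders 0, 1, 2; the structure tensor takes gradients from a 3x3
Sobel of the sigma-smoothed image and smooths the tensor entries at the
same sigma before the closed-form 2x2 eigendecomposition; the
intensity-threshold family emits a 0/255 map at a per-image quantile
cutoff. Features are computed on the 8-bit normalized image, matching the
memory-saving 8-bit internal representation of the classical route, and
stored as doubles thereafter.

Normalization is per-image min-max with round-half-up quantization; a
constant image maps to all zeros (a constant carries no signal, and this
avoids a divide-by-zero). Per-image rather than global scaling is a
deliberate choice — it makes the pipeline invariant to the absolute phase
offset of an acquisition — and is recorded in `normParams` so it can be
audited or replaced.

## Classical backends

Hyperparameter defaults are fixed at the published working point:

* **RF** — 100 trees (ranger, probability forest, impurity importance).
* **XGB** — 100 rounds, max depth 4, subsample 0.5, logistic objective.
* **SVM** — polynomial kernel, degree 3, gamma = 1/(k Var(X)) ("scale"
  heuristic); cache 5000 MB. The advertised 1000-iteration cap has no
  equivalent in libsvm's solver, so it is carried as an inert setting.
* **MLP** — hidden layers (50, 25), ReLU, Adam, at most 1000 epochs with a
  50-epochs-without-improvement halt. No installed R package provides a
  two-hidden-layer ReLU/Adam perceptron, so the package implements the
  dense-network engine itself; inputs are standardized internally because
  raw 8-bit feature scales saturate the sigmoid head.
* **LDA** — singular-value-decomposition path (`MASS::lda`); features that
  are constant within both classes are dropped before the fit, mirroring
  the tolerance behaviour of an svd solver on degenerate directions.

Thread counts (25 in the published table) are hardware-specific and are
treated as advisory caps: execution uses
`min(n_threads, getOption("dropseg.max_threads", 1))`, so results are
reproducible on a single CPU by default. All stochastic backends take an
explicit seed (default 0). Class imbalance is left unweighted on purpose:
the droplet class occupies a few percent of pixels and the behaviour of
the methods under that imbalance — including the all-negative failure mode
of the CNN — is part of what the package studies.

Score maps are probability-like in [0, 1] for every backend so that one
ROC interface covers all six methods: tree ensembles and the MLP emit
probabilities directly, LDA emits posteriors, and SVM decision values are
mapped through a logistic squashing (the binary mask still uses the SVM's
native class prediction; how the original work thresholded SVM decision
values is unstated, so the native sign rule is assumed).

## The U-Net dialect

The published description fixes the encoder/decoder skeleton (paired 3x3
same-padded ReLU convolutions at widths 64/128/256/512, 2x2 max pooling,
a 1024-wide bottleneck at 16x16, 0.5 dropout at the two deepest blocks,
2x2 upsampling with skip concatenation at every level, a sigmoid output
head) plus one hard constraint: 31,031,685 trainable parameters. Several
U-Net variants fit the prose; the dialect implemented here — a 2x2
up-convolution after non-learned nearest upsampling, a two-filter 3x3
penultimate convolution, a 1x1 sigmoid output, biases everywhere —
reproduces the printed parameter total exactly, which is why it was
chosen. `countTrainableParameters(buildUnet())` recomputes the sum by
walking the layer graph, and the test suite checks it against a
closed-form per-layer formula.

Because no deep-learning framework is available to R here, the package
carries its own training engine: im2col GEMM convolutions with a
hand-derived backward pass (verified against finite differences in the
suite), 2x2 max-pool/upsample pairs with exact gradient routing, inverted
dropout, Adam, and binary cross-entropy. Choices the published work leaves
open are set as conservative defaults and recorded in the `TrainRecord`:
optimizer Adam with learning rate 1e-4, batch size 2. Dropout applies
after the convolutions of the 512 block (before pooling) and after the
bottleneck, and is active only during training, so inference is
deterministic. Inputs share the classical route's normalization path:
8-bit min-max, divided by 255. Images smaller than the canvas are
zero-padded (background phase is ~0) with centred borders, odd remainders
going right/bottom, and predictions are un-padded back exactly.

The probability cutoff for the final mask is 0.7 (>= rule), as published.
The `reducedUnetConfig()` — all widths divided by 8, canvas 64 — is a
first-class configuration: it preserves every structural property
(including the parameter-count formula) at roughly 1/1000 of the compute,
and is what the test suite trains. The full 256x256 network builds and
counts correctly but is not trained in the suite; training it for 1000
epochs is a GPU-scale undertaking.

## Metrics and protocols

The six scores are computed from exhaustive pixelwise confusion counts.
Scores with a zero denominator (e.g. precision when nothing is predicted
positive, or any droplet score on an image with no droplets and no
predictions) are NaN, flagged "uninterpretable", excluded from averages,
and the exclusion counts are reported — silently coercing them to 0 or 1
would bias exactly the imbalanced-class comparisons the package exists
for. The ROC sweep visits every distinct threshold; AUC uses the
Mann-Whitney convention (ties count one half) and equals the
pairwise-ranking probability, which the suite verifies by brute force.

Cross-validation uses contiguous folds in input order (no shuffling),
with larger folds first when the item count is not divisible by k; the
remainder rule is arbitrary but fixed for determinism. Per-fold scores are
per-image means (pooled pixel counts per fold are also emitted, since
whether published averages pool pixels or average images is ambiguous;
per-image means weight small and large cells equally). The
training-size sweep draws seeded subsamples from a training pool disjoint
from a fixed test set and reports the median per-test-image Dice.

Desk-scale defaults stand in for the full published protocol (5000
training / 2000 test images at 256x256): the suite uses 150 training / 60
test synthetic scenes at 64x64 for the classical route and 200 scenes for
the reduced U-Net, sizes at which the whole suite runs on one CPU in
minutes while still exercising every code path at realistic class
imbalance. The full-scale protocol remains available through the same
configuration objects.

## Known limitations

* The 80-filter parameterization is a reconstruction of the named filter
  families, not a verbatim copy of an undisclosed list; rankings of
  feature importance will differ in detail from any other bank.
* The SVM backend exposes no iteration cap, so pathological inputs can be
  slow; the polynomial-kernel SVM is also the method that fails this
  segmentation task, which the suite only exercises at small scale.
* The U-Net engine is CPU-only and single-threaded apart from BLAS; it is
  meant for the reduced configuration and for correctness, not for
  full-scale 1000-epoch training.
* Synthetic scenes are a controlled stand-in for real QPI data; see the
  generator section for what they deliberately omit.
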