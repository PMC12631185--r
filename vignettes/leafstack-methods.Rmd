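---
title: "Hybrid feature stacking for leaf disease classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid feature stacking for leaf disease classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafstack)
```

## The problem and the model

Foliar disease alters leaves in three visually distinct ways: discoloration
(color), spotting and surface micro-patterns (texture), and deformation of
the outline (shape). `leafstack` classifies single-leaf RGB images taken
under controlled conditions (uniform background, flat leaf) by combining two
complementary representations and refining a classical classifier's output
with a neural meta-learner:

1. **Handcrafted descriptors.** After a bilinear resize to 224 x 224 pixels,
   six fixed blocks are concatenated into a 321-dimensional vector:
   per-channel HSV and LAB histograms
   ($H_c(b) = \sum_i \delta(I_c(i) \in b)$, 8 bins per channel), the three
   dominant colors from k-means over RGB pixels (centroids
   $C^* = n_j^{-1} \sum_{i \in j} x_i$ plus cluster proportions), the
   256-bin local binary pattern histogram
   ($\mathrm{LBP}_{P,R} = \sum_p s(g_p - g_c)\,2^p$, $s(z) = 1$ iff
   $z \ge 0$, $P = 8$, $R = 1$), gray-level co-occurrence contrast
   $\sum_{i,j} (i-j)^2 P(i,j)$ and angular second moment
   $\sum_{i,j} P(i,j)^2$, and shape area / perimeter / circularity
   $C = 4\pi A / P^2$ from an Otsu-based segmentation.
2. **Deep features.** A convolutional backbone reduced by global average
   pooling, $f_\mathrm{deep} = \mathrm{GAP}(\phi(x;\theta))$. The backbone
   is pluggable: the built-in surrogate is a seeded random-weight
   convolutional network (three stride-2 3x3 layers, ReLU, default 64
   output channels), and an `external` adapter accepts any user-supplied
   feature function (e.g. a pretrained residual network cut at its pooling
   layer). Everything downstream is backbone-agnostic.
3. **Fusion and reduction.** The fused vector
   $F = [f_\mathrm{trad} \,\|\, f_\mathrm{deep}]$ is standardized and
   compressed by PCA: covariance $C = X^\top X/(n-1)$, eigendecomposition
   $C v_i = \lambda_i v_i$, projection $Z = X W_k$.
4. **Stacking.** A base learner (one of random forest, two gradient-boosted
   tree profiles, k-nearest neighbors, or multinomial logistic regression)
   produces class probabilities $p = M(Z)$, which feed a dense network head
   — Dense(512, ReLU), Dense(256, ReLU), Dense(128, ReLU) with dropout 0.3
   after each hidden layer, and a softmax output over the $m$ classes
   ($z^{(l)} = W^{(l)} a^{(l-1)} + b^{(l)}$, $a^{(l)} = g(z^{(l)})$,
   $\hat y_j = e^{z_j} / \sum_c e^{z_c}$).
5. **Explanation.** A tabular LIME variant fits a K-sparse, kernel-weighted
   ridge surrogate ($\pi_x(z) = \exp(-D(x,z)^2/\sigma^2)$) to the stack's
   probability for one class around one instance.

## Design choices where the design was open

Several knobs are conventions of this package rather than forced by the
method; each is a configurable parameter.

* **Histogram bins (B = 8 per channel).** Coarse enough that a 224^2 image
  populates bins densely; LAB channels are mapped to [0, 1] via L/100 and
  (a|b + 128)/255 before binning, HSV channels are natively [0, 1].
* **LBP (P = 8, R = 1, integer offsets, no interpolation).** The canonical
  3x3 operator; neighbors are read counter-clockwise starting from the
  right-hand neighbor, and only pixels with a complete ring contribute.
  This keeps hand-computed oracle values exact.
* **GLCM (L = 8 levels, distance 1, four angles averaged, symmetric,
  normalized).** Averaging 0/45/90/135 degrees gives rotation robustness at
  negligible cost.
* **Dominant colors.** Lloyd's k-means (k = 3) with k-means++ seeding;
  clusters are reported in descending size with lexicographic tie-breaks,
  so "the dominant color" is the first centroid. Images with at most k
  distinct colors are solved exactly, which doubles as the degenerate-input
  (empty-cluster) policy: unused centroids replicate the dominant color
  with proportion zero.
* **Segmentation.** Otsu threshold on BT.601 luma; the foreground is the
  binary class with fewer border-touching pixels (robust to contrast
  polarity); then largest 8-connected component and hole filling. Images
  that cannot be segmented (constant images) yield a zero shape block and a
  warning instead of aborting a batch.
* **Perimeter.** The outer boundary is Moore-traced, smoothed with a
  5-point circular moving average, and offset outward by half a pixel
  (adding $\pi$ to the closed-curve length). A raw crack-boundary length
  overestimates oblique arcs by up to ~8%, which would push disk
  circularity to ~0.88; the smoothed estimator measures disks of radius
  30-120 at circularity 0.994-0.995 (spread < 1%), a 50-pixel square
  within 5% of the ideal $\pi/4$, and a 2:1 ellipse within 0.5% of its
  Ramanujan-perimeter reference.
* **Standardize before PCA.** The handcrafted blocks (histogram fractions,
  pixel areas in the thousands) and deep activations live on wildly
  different scales; unstandardized PCA would be dominated by the shape
  block. Zero-variance columns get unit scale. The retained dimension is
  the smallest k reaching 95% cumulative variance unless set explicitly;
  when d > n the Gram-matrix decomposition is used (identical nonzero
  spectrum). Eigenvector signs are fixed so each component's
  largest-magnitude loading is positive, making projections reproducible.
* **Out-of-fold stacking.** The head's training inputs are stratified
  5-fold out-of-fold probabilities: in-sample probabilities from a strong
  base learner are near-one-hot and would leak labels into the meta-learner.
  A `naive` flag reproduces the literal single-pass protocol for
  comparison. The base learner is refit on the full training split for
  inference, and its probabilities on the validation split drive early
  stopping.
* **Head training.** Cross-entropy, Adam (learning rate 1e-3), batch 32, at
  most 300 epochs, early-stopping patience 30 with best-weight restoration,
  He-uniform initialization, inverted dropout. All of it is seeded; two
  fits from one master seed are identical.
* **Base-learner defaults.** rf: 100 trees, sqrt(d) features per split;
  xgb: 100 rounds, depth 6, learning rate 0.3, L2 lambda 1; gb: the
  classical gradient-boosting profile (100 stages, learning rate 0.1,
  depth 3, no L2); knn: k = 5, Euclidean, vote-fraction probabilities;
  lr: multinomial softmax regression with L2 strength 1.0 trained by
  full-batch gradient descent (up to 1000 iterations). Both boosted
  profiles run on the same tree-boosting engine, distinguished only by
  these hyperparameters.
* **LIME.** Perturbations are Gaussian in standardized units around the
  instance (a mask-to-mean binary scheme was rejected because it destroys
  locality for continuous PCA features); kernel width defaults to
  $0.75\sqrt d$; sparsity is realized as hard K-selection by absolute
  kernel-weighted covariance followed by ridge (penalty 1.0); the surrogate
  response is the explained class's probability, not its logit. Fidelity is
  the kernel-weighted R^2.
* **Splitting.** 70/15/15 stratified by class with largest-remainder
  apportionment; remainder ties resolve in train-validation-test order, so
  a class of 10 splits 7/2/1.
* **Undefined metrics.** Precision or recall with an empty denominator is
  reported as 0 with a warning (keeping weighted averages defined); one-vs-
  rest AUC for a class with no positives or no negatives is excluded from
  the macro average rather than imputed at 0.5.

## What the synthetic generator emulates — and what it does not

`generate_leaf_image()` renders a centered ellipse (the leaf) on a dark
uniform background, with class-dependent base hue, eccentricity,
non-overlapping circular lesions (count, color, radius ranges), and
additive Gaussian texture noise confined to the leaf. This reproduces the
statistical hooks each descriptor block needs — color shifts for the
histograms and dominant colors, noise and spotting for LBP/GLCM, outline
elongation and lesion geometry for the shape block, a segmentable
foreground for the mask — under full determinism: every image is a pure
function of its class specification and seed.

It does **not** attempt photorealism: no venation, no perspective, no
shadows or occlusion, no field conditions, and lesions are ideal disks.
Passing tests on these fixtures therefore demonstrate that the pipeline's
mathematics and plumbing are correct and that it separates classes whose
signal matches its feature blocks — not that any particular accuracy will
transfer to real crop imagery, which additionally requires a pretrained
backbone supplied through the `external` adapter.

`generate_feature_table()` is the analogous fixture one level up: spherical
Gaussian classes whose means sit `separation * noise_sd` apart (placed on
distinct coordinate axes when the class count allows, so pairwise spacing
is exact). `separation = 0` is a guaranteed-signal-free control, used to
verify that every stage honestly reports chance-level performance.

## Numerical conventions and degenerate inputs

* Eigenvalues are clipped at zero (numerical negatives set to 0) and sorted
  descending; component orthonormality is held to 1e-8.
* Probability matrices are renormalized row-wise after each stage and
  asserted row-stochastic to 1e-9; softmax is computed with max-shift
  stabilization.
* Argmax ties break toward the lowest class index; class order is
  lexicographic everywhere.
* All derived seeds come from one master seed through a fixed
  multiplicative-congruential mix kept below 2^31.
* Constant images: unsegmentable (warning + zero shape block); their LBP
  mass sits entirely at code $2^P - 1$ because ties count as
  "greater-or-equal"; their co-occurrence matrix is a point mass (contrast
  0, ASM 1).

## Problem sizes used in the shipped tests

The test-suite and acceptance studies run at deliberately compact sizes
chosen to exercise every code path: feature-table studies at 200 points per
class in 10 dimensions over 3 classes (separations 0/1/6); image studies at
3-4 classes with 8-9 images each at 112-128 pixels; the PCA/SVD
cross-check at 120 x 20; the null-AUC calibration at n = 2000. The
end-to-end determinism study runs the identical configuration twice and
compares report bytes.

## Known limitations

* The surrogate backbone is a fixed random projection: useful deep features
  for real imagery require external pretrained weights via
  `backbone_spec(kind = "external")`.
* Single-leaf scenes only; no multi-leaf layout, occlusion or background
  clutter handling.
* LBP is the plain (non-uniform, rotation-variant) operator; GLCM is
  summarized by contrast and ASM only.
* The gradient-descent logistic learner is full-batch and can be slow far
  beyond the tested scales; swap in the boosted or forest learners for
  large problems.
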