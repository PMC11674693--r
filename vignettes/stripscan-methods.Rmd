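---
title: "Texture-based quantification of lateral flow assay strips: methods and design choices"
author: "stripscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stripscan methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A colorimetric lateral flow assay (LFA) reports analyte concentration
through the darkness of a *test line* printed on a nitrocellulose
membrane; a *control line* confirms the assay ran. Reader-acquired strip
images are commonly quantified by mean line intensity, which is fragile
under illumination and background variation. `stripscan` instead
classifies strips by **texture**: the spatial co-occurrence statistics of
gray levels inside the diagnostic line regions. The target labels are
eight thyroid-stimulating-hormone (TSH) concentration levels
(0.5, 1, 2.5, 5, 10, 25, 50, 100 mIU/L).

## Pipeline overview

1. **Standardise**: orient the strip with the long axis horizontal and
   resize to 500 x 128 px by exact area averaging.
2. **Segment**: split the image into two 250 x 128 halves and threshold
   each half independently with Otsu's between-class-variance criterion.
   Per-half threshold selection is the "adaptive window" element: a
   single global threshold cannot accommodate the intensity difference
   between the two line regions. The line ROI in each half is the
   largest 8-connected foreground component.
3. **Patches**: cut four 128 x 32 patches per image, two per line ROI,
   centred on the ROI centroid at column offsets −8 and +8 so each patch
   contains the line plus flanking membrane. 800 images become 3200
   labelled patches.
4. **AHMO-GLCM**: quantise each patch to 64 gray levels over its own
   range, compute one horizontal gray-level co-occurrence matrix per
   offset d = 1..25, normalise each to unit mass, and average them into
   a single 64 x 64 matrix.
5. **Features**: 22 Haralick-style scalars per patch.
6. **Selection / CNN**: mRMR ranks the 22 features (top 9 kept); a small
   convolutional network over the 22-vector provides a learned
   192-dimensional representation ("CNN features").
7. **Classification**: eight classical classifiers are trained on each
   of the three feature sets (All / MRMR / CNN) and evaluated on a
   stratified 70/15/15 train/validation/test split.

## The averaged multi-offset co-occurrence operator

For a quantised patch `q` with `Ng` levels, the GLCM at offset `d`
counts ordered horizontal pairs `(q[r, c], q[r, c + d])`; the total count
at offset `d` is `rows x (cols − d)`. The averaged operator is

    p = (1 / dmax) * sum_d C_d / |C_d|,   d = 1..dmax

i.e. **normalise each offset's matrix before averaging**. The
alternative (summing counts, then normalising once) weights offset `d`
by its pair count, so short offsets would dominate; equal per-scale
weighting is the default and the count-weighted variant is one config
switch away (`average = "counts"`). Pairs are ordered (non-symmetric) by
default; symmetric counting adds the transpose.

Quantisation maps the patch's own gray range `[gmin, gmax]` linearly
onto levels `0..Ng−1`, each value to its closest level (a constant patch
maps to level 0). Per-patch ranging makes the operator invariant to
affine illumination changes within a patch; a fixed 0–255 mode exists
for cross-image comparability studies. With 32-column patches the
largest offset d = 25 still leaves 7 pairs per row.

## The 22 texture features

Gray-level indices run 1..Ng, so the sum distribution p(X+Y) has support
2..2Ng and the absolute-difference distribution p(X−Y) has support
0..Ng−1. Logs are base 2. The machine-epsilon guard (2⁻⁵²) is applied to
zero probabilities only, so degenerate matrices give exact entropies
(a single-cell matrix yields energy 1, entropy 0, contrast 0,
homogeneity 1). Correlation returns 0 when a marginal is degenerate, and
the information measures return 0 when both marginal entropies vanish;
all 22 features are finite for every normalised matrix with Ng >= 2.

Decisions where conventions genuinely diverge:

* `indnc` is computed as `sum p/(1 + (i−j)^2)` under the default
  `strictPrintedFormulas = TRUE` — identical to `homop` — because that
  closed form is the one this pipeline fixes; the library-standard
  normalised form `sum p/(1 + |i−j|/Ng)` is the `FALSE` variant.
  `idmnc` always uses the Ng²-normalised form.
* The cubic central moment of i+j is cluster shade (`cshad`), the
  quartic is cluster prominence (`cprom`).
* Difference entropy is computed over p(X−Y)'s true support 0..Ng−1.
* Sum variance `svarh` is the second moment of p(X+Y) about the sum
  average (`savgh`), not about the sum entropy (the latter appears in
  some historical texts and is widely regarded as a typo); sum-of-squares
  variance `sosvh` is taken about the row-marginal mean.
* `savgh` is exported as the plain sum average.

Every feature is oracle-tested against an independent naive double-loop
implementation on random matrices (agreement to 1e-10).

## mRMR

Features are discretised by rank into 16 equal-frequency bins, which
makes the ranking invariant under strictly monotone transforms.
Relevance is mutual information with the class label; the greedy
criterion is MI-difference (MID): each pick maximises
`I(f; label) − mean I(f; selected)`. The quotient variant (MIQ) is a
config option. Ties break towards the earlier column, so the ranking is
bitwise reproducible. By default selection runs on the training
partition only, to avoid information leaking from the test partition
into the feature set; full-data selection is available.

## The tabular CNN

Each 22-feature vector is treated as a (22, 1, 1) image. The network is
conv(3x3, "same") → batch-norm → ReLU, three times with 8/16/32 filters,
max pooling (2x2, stride 2, padding (top, bottom, left, right) =
(0, 1, 0, 1)) after the first two blocks, then flatten → fully connected
(8 units = classes) → softmax. The pooled length follows
`floor((size + padSum − window)/stride) + 1`: 22 → 11 → 6, so the
penultimate representation has 6 x 1 x 32 = 192 activations — the
exported "CNN features". Training is stochastic gradient descent with
momentum 0.9, learning rate 0.01, batch size 32, at most 10 epochs, data
reshuffled each epoch, with per-epoch monitoring on the validation
partition. Features are z-scored with training-split statistics before
entering the network.

Implementation note: with input width 1, the outer columns of a 3x3
"same"-padded kernel only ever multiply zero padding, so the
convolution is implemented as its exact mathematical equivalent — a
length-3 1-D convolution along the 22-axis — in base R matrix
operations. Filter counts (8, 16, 32), the momentum coefficient, the
pooling placement (after blocks 1 and 2, none after 3) and the use of
the penultimate flatten as the feature layer are this package's fixed
choices where reasonable alternatives exist; all are configurable.

## Classifier battery and metrics

Eight classifiers with fixed documented presets: RBF SVM (one-vs-one,
gamma = 1/p), wide and medium neural networks (single hidden layer of
100 / 25 ReLU units trained by mini-batch SGDM, lr 0.01, momentum 0.9,
60 epochs — implemented in-package for speed and determinism at these
widths), LDA with pooled covariance, bagged trees (30 trees, mtry = p),
k-NN (k = 10, Euclidean), boosted trees (30 rounds, depth 3), and
Gaussian naive Bayes. Classical models train on the 70% partition only;
the 15% validation partition is reserved for the CNN's per-epoch
monitoring; all models are compared on the same 15% test partition.

Metrics pool per-class one-vs-rest TP/FN/FP/TN counts over the K = 8
classes (**micro averaging**) before forming sensitivity, specificity
and accuracy. Two identities follow algebraically and are asserted on
random confusion matrices: micro sensitivity equals accuracy (both are
trace/total), and pooled specificity equals `1 − (1 − accuracy)/(K − 1)`
— e.g. accuracy 97.29% pairs with specificity 99.61%. Macro averaging is
available as an option.

## The synthetic strip generator

Real reader datasets of graded TSH strips are not generally available,
so the package ships a generator whose defaults define the study
conditions used by the tests:

* 700 x 145 px strips, membrane background at gray 205 with i.i.d.
  grain noise (sd 3) and a mild linear illumination ramp (amplitude 3);
* a control line (fixed position, left half) and a test line (right
  half), both 20 px wide;
* test-line depth strictly increasing over the eight labels
  (25, 35, ..., 95 gray levels), with spatially correlated speckle whose
  standard deviation (1.5 x label index) and correlation length grow
  with concentration, so texture as well as intensity carries class
  information;
* **conjugate depletion**: at higher analyte more gold conjugate is
  captured at the test line, so the control line prints lighter
  (depth x (1 − 0.05 (l − 1)) at label index l) and its speckle
  coarseness mirrors the test line's. This matters because half of all
  patches come from the control line: were the control line strictly
  concentration-invariant, those patches would be unclassifiable and
  overall patch accuracy could not exceed ~56% no matter the method.
  Depletion is a real sandwich-assay phenomenon and is switchable off
  (`controlDepletionRate = 0`).

The generator emulates geometry and first/second-order statistics, not
physics: no binding kinetics, membrane flow, optics, or fluorescence.
Consequently, passing tests demonstrate that the pipeline recovers the
class signal it is pointed at — not that the specific defaults
reproduce any particular instrument's images.

A **null configuration** (`nullStripParams()`: constant depth map, no
speckle, no depletion) makes the per-label image distributions
exchangeable; end-to-end accuracy must then be statistically
indistinguishable from chance (12.5%). The null check uses a single
representative classifier (LDA on all 22 features): taking the maximum
over 24 classifier-feature combinations on null data would be biased
above chance by selection.

## Numerical and convention choices

* Intervals are 1-based and closed throughout (R convention); the ROI
  bounding box `(rowMin, colMin, rowMax, colMax)` is inclusive and the
  patch window arithmetic is documented in those terms.
* Area-weighted resizing is exact overlap averaging (two weight-matrix
  multiplications); it preserves constants and the [0, 255] range, and
  resizing an image already at target size is the identity.
* Otsu threshold: the between-class-variance maximum can be flat across
  empty histogram gaps; the first maximum is taken (deterministic), and
  any threshold in the flat region induces the same segmentation.
* Connected components are 8-connected (row-run union-find); ties on
  equal component size break towards the leftmost bounding box.
* Max-pool ties take the first element of the window.
* A single master seed fans out to per-stage seeds deterministically;
  changing the master seed changes stochastic outputs but never shapes
  or schemas.

## Problem sizes

The default study size is 100 images per label (800 images, 3200
patches; split 2240/480/480). The test suite exercises the full default
size in its end-to-end checks and reduced sizes (3–40 images per label)
elsewhere; the null-configuration check uses 40 images per label, which
gives a 192-patch test partition and a ±4.7-percentage-point binomial
band around chance.

## Known limitations

* The synthetic generator's appearance statistics are plausibility
  choices, not fits to reader data; absolute accuracies on real strips
  will differ.
* Per-patch quantisation discards absolute intensity, by design; if
  absolute darkness is the only discriminating signal and texture is
  flat, the fixed-range quantisation mode should be used instead.
* The CNN is intentionally tiny and CPU-bound; it is a feature
  extractor, not a tuned classifier.
* `indnc` under the strict printed form duplicates `homop`; downstream
  feature selection treats them as the redundant pair they are.
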