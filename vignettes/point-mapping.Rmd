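---
title: "Point-mapping segmentation of the dorsal tongue surface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-mapping segmentation of the dorsal tongue surface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonguemap)
```

## The problem and the method

The dorsal surface of the tongue is covered by specialised mucosa whose
visual texture — the quasi-regular pattern of filiform and fungiform
papillae — changes under many local and systemic conditions: fissuring,
papillary atrophy, keratotic plaques, coating, erosions and ulcers all
disrupt the normal papillary pattern. Because such changes are irregularly
and unpredictably distributed across the surface, they are awkward targets
for dense semantic segmentation (U-Net-style models need consistently
shaped, consistently labelled objects and far more annotated data than a
clinic typically has).

*Point-mapping segmentation* sidesteps this. A photograph of the tongue is
tiled by an overlapping grid of small square crops; each crop is resized to
the classifier input (96 × 96 pixels) and classified into one of three
classes — **abnormal** mucosa, **normal** mucosa, or **other** (non-tongue:
lips, teeth, background). A colour dot (blue / green / red respectively) is
placed at the centre of each tile, and the resulting grid of class-coloured
dots is the segmentation. With the default 16 × 24 grid, each photograph
yields 384 classified points.

The pipeline in this package mirrors that workflow end to end:

1. **Grid cropping** (`grid_crop()`): training photographs are divided into
   48–180 non-overlapping square regions (e.g. 8 × 12 on a 2592 × 3872
   image gives 96 crops of 324 × 323 pixels), so that each crop contains a
   similar density of papillae regardless of photographic magnification.
2. **Patch dataset** (`assign_splits()`, `dataset_summary()`): crops are
   labelled abnormal / normal / other, split into training (68.8%),
   validation (15.4%) and test (15.8%) sets, and the training split is
   augmented ×4 by horizontal flip, vertical flip and 90° rotation.
3. **Patch classifier** (`train_classifier()`): a pluggable 3-class
   classifier trained with SGD (learning rate 0.005, momentum 0.9),
   categorical cross-entropy, dropout 0.5, 50 epochs.
4. **Point mapping** (`predict_pointmap()`, `ground_truth_pointmap()`,
   `render_pointmap()`): overlapping 16 × 24 tiling, per-tile prediction,
   dot rendering; ground truth derives from expert annotation masks painted
   blue (abnormal) and green (normal) over the photograph.
5. **Evaluation** (`classification_report()`, `seg_counts()`,
   `macro_average()`, `voc_ap()`): confusion-matrix metrics for the patch
   classifier, point-count IoU metrics and PASCAL-VOC average precision for
   the segmentation.

## Evaluation mathematics

**Patch classification.** From the 3 × 3 confusion matrix (rows actual,
columns predicted, classes ordered abnormal / normal / other) each class is
scored one-vs-rest: TP is the diagonal entry, FP the rest of its predicted
column, FN the rest of its actual row, TN everything else, and

$$\mathrm{precision} = \frac{TP}{TP+FP},\quad
  \mathrm{recall} = \frac{TP}{TP+FN},\quad
  F_1 = \frac{2PR}{P+R},\quad
  \mathrm{accuracy} = \frac{TP+TN}{TP+TN+FP+FN}.$$

One-vs-rest AUC is available through the rank (Mann–Whitney) statistic
(`roc_auc()`).

**Point-count segmentation.** For one class on one image, with $G$ the
number of ground-truth points, $P$ the predicted points and $I$ their
intersection, the union is $S = G + P - I$ and

$$TP = I,\quad FP = P - I,\quad FN = G - I,\quad
  \mathrm{IoU} = I/S,\quad
  \mathrm{precision} = I/P,\quad \mathrm{recall} = I/G.$$

Counting is done in grid points rather than rendered-dot pixels: every dot
has identical area, so pixel counts are a constant multiple of point counts
and the constant cancels from every ratio. Note that $TP = I$ (not $P-I$,
which is the false-positive count); this is the only assignment consistent
with $\mathrm{precision} = I/P$ and $\mathrm{recall} = I/G$.

Per-image metrics are macro-averaged over test images per class
(`macro_average()`), and the report's "mean" row is the unweighted mean of
the three class means.

**Average precision.** Each test image contributes one ground-truth
instance per class present ($G > 0$) and one detection per class predicted
($P > 0$), with confidence equal to the mean softmax probability of the
class over the points predicted as that class (`image_confidence()`; a
flag switches to averaging over all grid points). A detection is correct
when its point-count IoU is ≥ 0.5. Detections are ranked by descending
confidence — ties keep their input order — and AP is the area under the
monotone precision envelope (VOC 2010+ "all-point" interpolation; the
11-point VOC 2007 rule is available behind a flag, since conventions
differ between VOC releases).

Zero-denominator conventions: a precision with $P = 0$ is reported as 0
when $G > 0$ and as 1 when $G = 0$ (vacuous truth), mirrored for recall;
an IoU with $S = 0$ is 1. Flags are attached where a value was defined by
convention.

## The classifier backends

The heavy VGG16 / ResNet-50 / Xception backbones typically used for this
task are deliberately **not** reimplemented layer-for-layer: without the
clinical photographs or the trained weights, fidelity to a specific
architecture is untestable, and the contribution exercised here is the
pipeline *around* the classifier. `train_classifier()` therefore treats
the classifier as a contract with three backends:

* **`texture-baseline`** — six deterministic, flip- and rotation-invariant
  texture features (mean R/G/B, local-contrast energy, bright-blob density,
  edge density) with per-class centroids and softmax over negative
  standardised distances. Its closed-form "training" makes it a fast,
  fully reproducible oracle for the downstream test surface.
* **`small-cnn`** — a compact convolutional network trained from scratch:
  a fixed 4 × 4 average-pool stem (96 → 24 pixels, inputs centred at
  zero), three 3 × 3 convolution blocks (8, 16, 32 channels; ReLU; 2 × 2
  max-pool after the first two), global average pooling, dropout 0.5 and a
  softmax head. It is the minimal design consistent with the training
  recipe above that trains on one CPU in minutes, in pure R matrix
  arithmetic (im2col convolutions), and is bit-reproducible given the
  seed. Batch size 32 and the absence of early stopping are package
  defaults (the recipe leaves them open).
* **`external`** — an adapter around any `predict_fn(patch) -> probs`,
  used both for externally trained models and for the ground-truth oracle
  (`oracle_classifier()`) in end-to-end identity tests.

Probability ties at argmax resolve by the fixed class order
abnormal > normal > other — conservative toward flagging pathology. The
same order breaks plurality ties in `label_region()`.

## The synthetic scene generator

No clinical image archive is distributed with tongue-surface studies, so
the package generates its own test imagery (`generate_scene()`,
`fixture_suite()`, `generate_patch_benchmark()`). A scene is a dark
textureless background, an elliptical tongue carrying a pink base with a
jittered bright-dot lattice (the papillae surrogate), and abnormal patches
with dedicated textures for four of the ten abnormality categories:

| type | texture |
|---|---|
| papillary atrophy | smooth, redder, near-textureless |
| fissures | pink base with dark sinusoidal grooves |
| hyperkeratotic change | bright, low-chroma plaque |
| tongue coating | whitish-yellow speckle |

The remaining categories (erosion, ulcer, hairy tongue, hypertrophy,
lichenoid change, artifacts) are representable through the generic
abnormal-patch mechanism but have no dedicated texture. Every texture
boundary coincides with a mask class boundary by construction, and all
randomness flows from one seed through per-component derived streams, so
scenes are bitwise reproducible.

These textures are parametric and simple on purpose: the test surface
needs controllable class separability and pixel-exact ground truth, not
realism. Passing tests on this imagery therefore demonstrate that the
*pipeline* — cropping, labelling, mapping, counting, ranking — is correct;
they do not demonstrate that any classifier generalises to clinical
photographs, which vary in illumination, saliva reflections, motion blur
and inter-patient texture in ways the generator does not model.

## Numerical and design choices

* **Crop-dimension rounding**: nominal crop size is round-half-up of
  `width / n_cols` — on a 3872-pixel height divided into 12 rows this
  gives 323 where floor would give 322 and leave uncovered rows. The last
  row/column is adjusted to end exactly at the image border (clipped when
  the nominal grid overshoots, extended when it undershoots), so the union
  of crops always covers every pixel exactly once per axis segment.
* **Coordinates** are 0-based with half-open `[x0, x0 + w)` pixel
  intervals; regions are row-major (row varies slowest).
* **Overlapping-grid placement**: `x0(j) = round(j (W - w)/(n_cols - 1))`,
  so the first tile is flush with the top-left corner and the last with
  the bottom-right. Default tile size is `round(W/12) × round(H/15)`,
  matching the whole-tongue training grid so that test tiles have the same
  magnification as training patches; both are caller-overridable because
  the magnification-to-grid rule is a free parameter of the method.
* **Resize kernel**: bilinear (the conventional choice; identity inputs
  are returned byte-for-byte).
* **Ground-truth point labels** summarise the tile's *full* pixel
  footprint (plurality rule), not just the centre pixel, because the
  classifier sees the whole footprint.
* **Annotation colour tolerance**: Euclidean RGB distance ≤ 60 to pure
  blue/green, absorbing JPEG compression of painted annotations.
* **Splitting** is photograph-grouped and stratified per class (a seeded
  greedy deficit-fill), so crops of one photograph never straddle
  train/test; for procedurally generated windows the grouping can be
  relaxed to record level, where the leakage guard is vacuous.
* **Report rounding**: 3 decimal places, half-up.

## Problem sizes used in the tests

The bundled tests and the acceptance script run entirely on synthetic
data at desk scale, chosen so the whole suite completes in a few minutes
on one CPU: 480 × 640 scenes, a 600-patch benchmark (200 per class), the
texture baseline on all 600, and the small CNN at 10 epochs on a 480/120
train/validation split (its training is also run twice to confirm
bit-reproducibility). The published evaluation tables bundled in
`inst/extdata` are replayed through the same metric code paths that the
synthetic pipeline uses, which is what ties the desk-scale verification to
the clinical-scale arithmetic.

## Known limitations

* Clinical generalisation is out of scope: no pretrained weights, no
  transfer learning, no GPU path, and no artifact handling (flash
  reflections, saliva bubbles) beyond what the generic abnormal-patch
  type can emulate.
* Only one annotation per photograph is supported; inter-rater
  variability is not modelled.
* Published per-class AUC values cannot be re-derived from a confusion
  matrix (they need per-patch scores), so `roc_auc()` is verified against
  constructed examples and an independent ROC implementation instead.
* One published report of this method states abstract-level AP figures
  (0.940 / 0.890) that disagree with its own per-class AP table
  (0.842 / 0.706); the table values are treated as canonical here and the
  discrepancy is left unreconciled.
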