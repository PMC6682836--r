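---
title: "Quantifying BI-RADS descriptors on breast ultrasound: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying BI-RADS descriptors on breast ultrasound: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usradiomics)
```

## The problem

Radiologists describe solid breast masses on B-mode ultrasound along the
five BI-RADS descriptor axes — shape, orientation, margin, echo pattern, and
posterior acoustic features — and these descriptors carry most of the
benign/malignant signal.  `usradiomics` turns each descriptor into one or
more deterministic, computable features of an image/mask pair, so that the
subjective lexicon becomes a ten-dimensional feature vector a classifier can
consume.  Segmentation is deliberately out of scope: the mask is an input
(a radiologist's manual delineation, or a phantom's ground truth), and no
speckle filtering or other preprocessing is applied to the image.

## Geometric conventions

All grids are R matrices indexed `[row, col]`, 1-based, with row 1 on the
skin side (depth grows with the row index).  Rectangles are stored half-open
on their upper bounds.  Contours are closed 8-connected pixel chains traced
with the Moore-neighbour algorithm, starting at the topmost-then-leftmost
boundary pixel and proceeding counter-clockwise in the Cartesian (y-up)
sense.  Straight segments are rasterized as digital lines by DDA with
half-up rounding; half-up (rather than R's round-half-even) keeps the
rasterization exactly translation invariant, which the feature suite relies
on.  Pixel-inclusion tests (equivalent ellipse, convex hull) use pixel
centres.

## The ten features

**Shape.**  `adee` compares the lesion with the ellipse sharing its centroid
and second central moments: semi-axes are twice the square roots of the
eigenvalues of the pixel-coordinate covariance — the construction that
reproduces a filled ellipse's own axes — and the value is the union area of
lesion and rasterized ellipse divided by the lesion area.  A perfect ellipse
scores ~1 (up to rasterization, tolerance 0.05 in the tests); irregular
shapes score higher.  Collinear masks have a degenerate moment ellipse and
are rejected.

**Orientation.**  The axis-aligned bounding-box ratio height/width.
Axis-aligned (rather than principal-axis) extents match the clinical
taller-than-wide reading, which is defined relative to the skin line.  The
transpose of a mask has exactly the reciprocal orientation.

**Margin sharpness.**  The mask is dilated and eroded with a disk of radius
20 px (`band_halfwidth`), giving outside and inside contours.  Every outside
contour pixel is paired with its nearest inside contour pixel (Euclidean;
ties broken by smallest (row, col)), the segment between them is rasterized,
and `Diff(i)` is the mean intensity of its outer half minus that of its
inner half (the middle pixel of an odd segment joins the inner half).
`avg_diff` is the mean over segments that stay inside the image; segments
that leave it are dropped and counted.  Perpendicular-offset pairing was the
other candidate; nearest-pixel pairing was chosen because it is well defined
at corners and concavities.  An erosion that empties — or disconnects — the
mask means the lesion cannot carry a band of that width, and is an error.

**Margin spiculation.**  The convex-hull boundary is densified to a pixel
chain (vertices alone would under-sample the profile) and, for every hull
pixel, the distance to the nearest lesion-contour pixel is recorded
(`v_convex`).  `num_peaks` counts the local maxima of this circular profile,
counting a plateau once and requiring a topographic prominence of at least
`peak_prominence = 2` px — without a prominence floor, rasterization jitter
of the hull chain inflates the count.  `avg_distance` is the profile mean
and `adch` the relative hull-area excess.  Convex masks score
`num_peaks = 0`, `adch ≈ 0`.

**Echo pattern.**  `echogenicity` is the mean intensity of a rectangle
concentric with the lesion bounding box and twice its height and width
(clipped to the image), excluding the lesion pixels and the posterior
rectangle, minus the mean lesion intensity.  Excluding the posterior
rectangle is the package's deterministic proxy for "exclude shadow areas":
no shadow detector is defined, so the region where an acoustic shadow would
fall is removed geometrically.  Note the sign: as defined, a hypoechoic
(dark) lesion has *positive* echogenicity.  The formula is implemented as
printed in the clinical literature it follows, even though the accompanying
verbal interpretation there ("positive = hyperechoic") has the opposite
sign; the package encodes the formula, not the sentence.  `entropy` is the
Shannon entropy (bits) of the empirical distribution of signed intensity
differences (right−left, down−up) over 4-neighbour pixel pairs lying fully
inside the mask.  Restricting pairs to the mask makes it a lesion property;
signed differences keep gradient direction information; a constant interior
gives exactly 0 bits.

**Posterior features.**  `shadow` is the mean intensity of the rectangle
directly below the bounding box (same columns, same height, clipped at the
bottom) minus the mean lesion intensity.  Negative values flag posterior
shadowing.  A lesion touching the bottom edge has no posterior region and
is rejected rather than imputed.

**Size** is the lesion pixel count, deliberately not rescaled for pixel
spacing: the feature mirrors raw-pixel practice across heterogeneous
scanners, and absolute calibration is unavailable in general.

All extraction is deterministic; there is no seed anywhere in the feature
path.

## The phantom generator

`generate_phantom()` emulates the five descriptor axes, not acoustic
physics: an ellipse (semi-axes along depth and lateral directions) whose
boundary radius is modulated by `n_spicules` cosine lobes with peak-to-valley
amplitude `spicule_depth` (tips protrude by half, valleys are carved by
half); constant tumour and background intensities; multiplicative
gamma-distributed speckle with a chosen coefficient of variation (the
standard first-order B-mode speckle proxy); Gaussian margin blur; and a
uniform intensity drop below the lesion across its column span for the
shadow.  The mask is the noiseless shape, so every phantom carries exact
ground truth.  What the phantom does *not* model — attenuation with depth,
anisotropic speckle, refraction edge shadows, heterogeneous internal echo
texture — bounds what green tests mean: they validate the geometry and the
pipeline mechanics, not clinical performance.

The default cohort (`generate_dataset()`) has 144 benign and 62 malignant
lesions, the class balance of a typical consecutive biopsy-proven series of
206 solid masses.  Benign lesions draw axis ratios in 0.4–0.8 (wider than
tall), 0–1 shallow spicules, little shadowing and mild blur; malignant
lesions draw ratios 0.9–1.6, 4–9 spicules of depth 8–16 px, strong
shadowing and heavier blur; both classes share the speckle range
(CV 0.06–0.1) and background intensities.  The classes are deliberately
separable but overlapping in individual features.  Semi-minor axes are kept
above ~24 px (after valley carving) for the malignant class so that every
phantom supports the default 20 px margin band; image size 256×256 leaves
the band and a posterior region inside the frame for all draws.

**When does `num_peaks` equal the spicule count?**  Only when the carved
valleys dominate the sag of the hull chord between adjacent tips.  On a
near-circular base of radius $R$ with peak-to-valley depth $A$ and tip
spacing $\theta = \pi/k$, the hull clears the base between tips when
$R \le (A/2)(1+\cos\theta)/(1-\cos\theta)$; otherwise the base ellipse
itself supports the hull mid-gap and splits the gap into several profile
peaks — a geometric property of the shape, not an estimator error.
`spiculated_params()` draws geometry at a safety fraction of this bound, and
the spicule-recovery checks use it; for strongly elongated lesions with few
spicules the equality is genuinely ill-posed, and the cohort relies only on
the (preserved, even amplified) class contrast in the count.

## Classification pipeline

`cross_validate()` assigns label-stratified folds keyed by sorted lesion id
(so fold membership is invariant to row order), deals classes round-robin
with a rotating offset (fold sizes differ by at most one), trains on k−1
folds and scores the held-out fold, and pools the out-of-fold scores into a
single ROC.  Pooling (rather than averaging per-fold AUCs) matches
single-operating-point reporting and is stable at cohort sizes of a few
hundred.  Features are z-scored with training-fold statistics for the
scale-sensitive methods (MLP, LDA, SVM); trees see raw features.

The five classifiers run with fixed, documented defaults — CART with Gini
splits; random forest with 100 trees and √p features per split; a
single-hidden-layer perceptron with 8 logistic units and up to 500
iterations; pooled-covariance LDA scored by class posterior; an RBF SVM
with C = 1 and γ = 1/(p·Var(X)), scored by the logistic of its decision
value.  These are reproducibility choices, not claims about any particular
historical implementation; all are overridable through
`classifier_spec(hyperparameters =)`.

`forward_select()` implements bottom-up selection: evaluate each feature
alone by pooled CV AUC, keep the best, then repeatedly evaluate adding each
remaining feature and keep the best candidate only if it strictly improves
the AUC, stopping at the first non-improvement.  Ties break by the
canonical feature order.  One consequence worth knowing: under a pure-noise
null the *maximum* over candidate deltas is positive with probability close
to 1, so the greedy trace almost always grows a step or two past the true
signal carrier, and its final AUC is optimistically biased.  For the same
reason the package's permutation-null check runs a *fixed* model
(`cross_validate` on all ten features) rather than the selection loop —
selection on permuted labels would not be expected to land at AUC 0.5.

`compute_roc()` computes the empirical ROC over observed thresholds (score ≥
threshold ⇒ malignant), the AUC as the tie-corrected Mann–Whitney statistic,
its 95% CI by the DeLong method, and the operating point maximizing
Youden's J, with ties resolved towards higher specificity and then towards
the higher cutoff; sensitivity and specificity carry exact Clopper–Pearson
intervals.  The returned cutoff is always an observed score or the +Inf
sentinel.

## Numerical and degenerate-input choices

Composition percentages round half away from zero to one decimal (printed-
table convention).  Masks must be single 8-connected regions; empty,
disconnected, or collinear masks, single-class label vectors, lesions
touching the bottom edge, and lesions thinner than the margin band all
raise named errors rather than NA-propagating.  Lesions whose extraction
fails inside `run_pipeline()` are excluded with a logged warning and
counted, not imputed.  A DeLong interval for a degenerate (perfectly
separated) score set collapses to [1, 1].

## Problem sizes used in the checks

The bundled verification suite runs the counting-oracle comparisons on ~20
constructed masks up to 64×64 and score sets up to n = 50; spicule-count
recovery on 60 phantoms (k = 3…8); parameter recovery on a 200-phantom
cohort; and the pipeline checks on the default 206-lesion cohort with
10-fold CV.  These sizes give stable pass/fail behaviour for the stochastic
checks while keeping a full run in the low minutes on one core.

## Known limitations

Clinical AUC/sensitivity/specificity values from any real cohort are not
reproducible here — phantom separability is a construction, and the
reported AUC ≈ 1 on the default cohort says nothing about clinical data.
The phantom texture model is first-order only.  `num_peaks` ground truth is
geometry-limited as described above.  Margin-band pairing is nearest-pixel,
which can map several outside pixels to one inside pixel on sharp
concavities.  No DICOM ingestion, no pixel-spacing calibration, no nested
CV or hyperparameter tuning.
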