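---
title: "Classifying oral lesion photographs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying oral lesion photographs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralscope)
```

## The problem

Early diagnosis of oral cancer and of oral potentially malignant disorders
(OPMDs) substantially improves survival, but expert assessment is scarce
exactly where the disease burden is highest. Smartphone photographs of the
oral cavity are an attractive screening signal, with two practical
obstacles: hand-held capture introduces large variability in lesion
position and apparent size, and clinical datasets are small and heavily
imbalanced (cancers are rare relative to ulcers and normal mucosa).

`oralscope` implements a complete five-class classification pipeline
(normal mucosa, aphthous ulcer, low-risk OPMD, high-risk OPMD, cancer)
built around two ideas:

1. **A centered capture protocol.** The photographer uses the camera's
   3x3 grid to frame the lesion inside the central cell, slightly smaller
   than the cell. Downstream, a fixed centered region-of-interest (ROI)
   crop then isolates the lesion plus its immediate mucosal context
   without any lesion detector or bounding-box annotation.
2. **Rotation/offset-center resampling.** Each training image is expanded
   into `3 x Nt` patches: rotations by `{-theta, 0, +theta}` about `Nt`
   slightly offset centers, with class-specific `Nt` chosen so the
   expansion simultaneously compensates capture variability (angle and
   centering error) and rebalances the classes. Patches are extracted by
   inverse mapping strictly inside the source frame, so — unlike naive
   rotation augmentation — no zero padding ever enters the training
   distribution.

The classifier is a convolutional backbone with a modified
representation head: a 1x1 convolution down to 5 channels, batch
normalization, and global average pooling emitting log probabilities
directly. The prediction is `c = argmax_j p_j(F(x))` with
`p = softmax(F(x))`. Because everything between the 5-channel map and the
logit is an average, the per-class pre-pooling map *is* a class
activation map: its spatial mean equals the class logit exactly, which
the CAM module exploits for visualization.

## Synthetic data as the test substrate

Clinical images cannot ship with a package, so the `synthetic_data`
module generates labeled images with the statistical and geometric
structure the pipeline assumes; every quantitative claim in the test
suite is exercised on this substrate.

Each image is a textured pink-mucosa background (smooth illumination
gradient, coarse mottling, pixel noise) with at most one procedural
lesion. The class signatures are deliberate caricatures of the clinical
descriptions — only class separability and geometry matter to the test
surface, not photorealism:

* **ulcer** — round yellow pseudomembrane core inside a red
  (erythematous) halo;
* **low-risk OPMD** — uniform flat pale patch, mildly irregular
  boundary, slightly translucent;
* **high-risk OPMD** — irregular pale patch with red components mixed
  in;
* **cancer** — dark, strongly textured nodular mass with shaded margins
  and a ragged boundary;
* **normal** — background only.

Canvas geometry is 4:3 and fully fractional, so any 4:3 size works; the
default canvas is 768x1024 and the test suite renders at 192x256 for
speed. Under the centered protocol the lesion center is uniform over the
central grid ninth and the diameter is drawn from `[0.5, 0.9]` of the
central-cell side ("slightly smaller than the cell", quantified here
since no number is given in the protocol description). Under the random
protocol the center is uniform over the whole frame (lesion kept inside).

Patient structure matters because splits are patient-disjoint: healthy
subjects contribute several images (different anatomic sites), lesion
patients about one. Per-patient image counts are drawn from a
zero-truncated Poisson matched to the requested per-class mean
(defaults 3.28, 1.15, 1.40, 1.32, 1.00 images/patient), which reproduces
the expected patient totals of a clinic-style dataset; only the mean is
specified, so the truncated Poisson is a modeling choice.

What the generator does *not* emulate: smartphone optics (focus, noise,
white balance), specular reflection, multiple lesions per image,
anatomic-site appearance differences, or inter-class ambiguity
(low-risk vs high-risk OPMD is genuinely hard clinically; the synthetic
classes are much cleaner). Passing tests therefore demonstrate that the
pipeline's machinery is correct and that its comparative claims hold on
data with the assumed structure — not that clinical-level accuracy would
be reached on real photographs.

## Preprocessing

The chain is: centered ROI crop, bilinear resize to a square, channel
normalization `(x/255 - mean_c) / std_c`.

* `roi_fraction` defaults to 0.5 — strictly larger than the 1/3 central
  grid cell, so the crop keeps mucosa around the lesion (context helps
  both experts and CNNs). The exact fraction used at clinical scale is
  not pinned down; it is a configuration value, not a constant.
* Channel statistics default to the conventional ImageNet values
  (0.485, 0.456, 0.406) / (0.229, 0.224, 0.225) because full-scale
  backbones are ImageNet-pretrained; they are configurable.
* All resizes (and rotated-patch sampling) use bilinear interpolation
  with the half-pixel-center convention, fixed once for reproducibility
  and checked against a scalar-loop oracle in the tests.

`simulate_random_positioning()` is the ablation baseline: a uniformly
random crop window of the same fraction, emulating capture without the
centering rule.

## Resampling geometry

`rotation_angles(theta)` returns exactly `{-theta, 0, +theta}` (one step
each direction, three patches per center); the default `theta = 15`
degrees. Offset centers are the image center plus `Nt - 1` points uniform
in a disc; default `Nt` per class is (1, 3, 3, 5, 15) with offsets
disabled for normals, so expanded counts obey
`expanded = base x 3 x Nt` exactly. With the study's training counts
(532, 175, 162, 89, 35) this yields (1596, 1575, 1458, 1335, 1575) — the
rebalancing is built into the `Nt` choice.

Two geometric quantities are not specified anywhere and are package
choices exposed in `resampling_config()`:

* **offset radius** — default 5% of the patch side: a small centering
  error, consistent with the protocol's premise that centering is
  approximately right;
* **patch side** — default is the largest square that stays inside the
  source under the worst-case rotation and offset, from the rotated
  square circumscription `s (cos theta + sin theta) + 2 r <= min(H, W)`.
  This makes the no-padding property hold *by construction*; the closed
  form bounds the geometric square and is conservative by at most ~2 px
  relative to the true sampling-grid bound (verified by corner tracing
  in the tests). The extractor independently asserts every sampling
  coordinate is in bounds and errors rather than pads.

Rotation is applied to the pre-crop source image (patches are windows on
the original frame); whether rotation preceded or followed ROI cropping
at clinical scale is not fully specified, and this choice is recorded in
the configuration.

`random_oversample()` is the comparison baseline: duplicate minority
rows until all classes match the majority count.

## Model and training

The desk-scale backbone (`tiny`) is four 3x3 stride-2 convolutions
(8, 16, 32, 64 channels) with ReLU — reduction factor 16, matching the
16-fold CAM upsampling. The full-scale network (HRNet-W18) is
deliberately not reimplemented: `make_backbone("hrnet_w18")` raises an
explicit error rather than silently substituting random weights, and a
full model can be supplied via `load_model()`. All forward/backward
arithmetic is vectorized base R over BLAS matrix products; gradients are
verified against finite differences in the test suite.

Head order is fixed as 1x1 conv, BN, global average pool, log-softmax:
taking the log after pooling is the only order that makes the pooled
output an exact log-probability vector. No nonlinearity follows the BN
(none is specified for the head); the head convolution is
zero-initialized so an untrained model scores cross-entropy exactly
`log 5` on any data. Prediction ties break toward the lowest class
index (the argmax rule leaves ties undefined; a fixed rule keeps results
reproducible).

Training is cross-entropy with SGD, Nesterov momentum 0.9, weight decay
1e-4. The full-scale schedule (the `train_config()` default) is initial
rate 0.001 "reduced by 30%" — interpreted as multiplied by 0.7, the
plain reading — at epochs 15, 30 and 45, batch 24, 100 epochs, five-fold
cross-validation. Folds partition *patients*, not images; image-level
folds would leak near-duplicate views of one patient across the split.
Whether cross-validation produces one candidate model per fold or is
used only for tuning is ambiguous at full scale; both are supported
(`folds > 1` selects the fold model with the best validation macro-F1;
`folds = 1` trains once against an explicit validation set). "Best
performing" is quantified as validation macro-F1, consistent with the
headline metric.

Desk-scale defaults used throughout the tests: 64x64 inputs, the tiny
backbone, learning rate 0.05 (from-scratch training of a small network
needs a larger rate than fine-tuning a pretrained one), at most ~18
epochs, 200 images/class. These sizes are the package's chosen study
conditions for its own claims; the ablation comparisons use matched
optimizer-step budgets (`max_steps`) so no arm sees more gradient
updates than another.

Augmentation follows the stated recipe: left-right flip, random
resize-crop with area ratio 0.7–1.0, brightness and contrast 0.9–1.1,
all seed-deterministic. Inference is a single forward pass in
evaluation mode — no test-time augmentation or ensembling.

## Evaluation

All metrics derive from the 5x5 confusion matrix (rows = truth). The
macro metrics are unweighted means over classes of one-vs-rest
sensitivity, specificity and precision; **macro F1 is the harmonic mean
of macro sensitivity and macro precision**, not the mean of per-class
F1 — the two differ and the package deliberately implements the former.
A per-class rate with a zero denominator (class absent from a degenerate
test set) is reported as 0 and flagged, keeping macro averages defined
without hiding the degeneracy.

One-vs-rest AUC is the normalized Mann–Whitney statistic with half
credit for ties. The 95% confidence interval uses the DeLong structural
components estimator (`var = var(V10)/m + var(V01)/n`), clipped to
`[0, 1]`; perfect separation gives a degenerate interval with a warning.
The implementation is cross-checked in the tests against both `pROC`'s
DeLong interval (agreement to 1e-10) and a 2000-replicate stratified
bootstrap (endpoints within 0.02 on n = 200).

## Class activation maps

`compute_cam()` returns the post-BN, pre-pooling channel for the
requested class, upsampled by the reduction factor (16) with bilinear
interpolation to the input size. Including the BN (evaluation mode)
makes the map/logit identity exact: `mean(raw map) = logit`, asserted
numerically in the tests. Maps are min-max normalized only for display
(`overlay_heatmap()`, fixed blue-to-red colormap, alpha blending); raw
maps are kept for quantitative use. On trained synthetic models the map
argmax falls inside the lesion for the large majority of correctly
classified cases, which is the qualitative "the network looks at the
lesion" check.

## Numerical and degenerate-input choices

* `theta = 0` collapses the angle set to `{0}`; offset radius 0 returns
  `Nt` copies of the center.
* Degenerate crops (side <= 1 px), out-of-bounds lesions, non-4:3
  canvases, unknown labels, mismatched label vectors, and out-of-range
  classes all raise errors naming the offending quantity.
* Every stochastic operation takes a seed; pipeline-level runs derive
  per-operation seeds from one global seed with stable tags
  (`derive_seed()`), so end-to-end runs are exactly reproducible and
  independent of call order.
* Bilinear sampling at exactly integer coordinates reproduces source
  pixels exactly, so angle-0 centered patches equal plain crops
  bit-for-bit.

## Known limitations

* The synthetic classes are far more separable than real clinical
  categories; desk-scale accuracies (>= 0.90) say nothing about clinical
  accuracy.
* The pure-R network engine is adequate for 64x64 desk-scale runs but is
  not a vehicle for 512x512 full-scale training.
* The no-padding bound is conservative by up to ~2 px (the geometric
  square circumscription rather than the exact sampling-grid bound).
* Patient structure is emulated only through image counts; no
  within-patient appearance correlation is modeled, so patient-disjoint
  splitting is exercised structurally, not statistically.
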