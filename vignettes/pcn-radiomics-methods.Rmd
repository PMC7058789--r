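---
title: "Methods: CT radiomics for pancreatic cystic neoplasm subtyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT radiomics for pancreatic cystic neoplasm subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Serous cystadenoma (SCA), mucinous cystic neoplasm (MCN) and intraductal
papillary mucinous neoplasm (IPMN) are the three common subtypes of
pancreatic cystic neoplasm. SCA is benign and managed by surveillance; MCN
and IPMN carry malignant potential and are candidates for resection, so the
preoperative call matters and is notoriously unreliable on conventional
reads of contrast-enhanced CT (CECT). `pcnradiomics` implements a complete,
testable radiomics workflow for this three-class problem: ROI
quantification into histogram/texture/wavelet features, robustness
screening against segmentation uncertainty, statistical and
shadow-attribute feature selection, and multi-class SVM / random forest /
neural network classification evaluated by per-class precision, recall, F1
and overall accuracy.

Because no patient images ship with the package, a synthetic phantom
generator stands in for the cohort. It is a first-class, tested module: its
defaults define the study conditions under which the pipeline's recovery
properties are asserted.

## Preprocessing and quantization

Volumes are resampled to a normalized 1 x 1 x 5 mm voxel grid (trilinear
for intensities, nearest-neighbour for masks, so masks stay binary).
ROI intensities are quantized to `n_levels = 64` equal-width bins over the
ROI's own min-max range:

    level(v) = min(64, 1 + floor(64 (v - min) / (max - min)))

A constant ROI maps to level 1. Min-max binning makes every downstream
feature invariant to affine intensity rescaling, which is the point of the
normalization: heterogeneous tube voltages shift and scale HU values but
should not move texture features. The resampler places voxel `i` at world
coordinate `(i - 1) * spacing`, so resampling onto the native spacing is an
exact identity and repeated resampling is idempotent.

## Feature families

Per image the package computes 47 features: 7 histogram statistics (mean,
variance, skewness, kurtosis, energy, entropy, uniformity of the level
distribution `p(i)`), 9 GLCM features (energy, contrast, entropy,
homogeneity, correlation, sum average, variance, dissimilarity,
autocorrelation), 13 GLRLM and 13 GLSZM features (the standard
short/long-emphasis, non-uniformity, percentage, low/high gray-level and
variance statistics), and the 5 Amadasun-King NGTDM features (coarseness,
contrast, busyness, complexity, strength).

Conventions that matter numerically:

* GLCM and GLRLM are accumulated over the 13 unique 3D directions and
  merged by summation before normalization, giving one matrix per family.
  GLCM counts both orderings of each pair (symmetric matrix); runs are
  truncated wherever a line leaves the ROI.
* GLSZM zones are 26-connected components of equal-level voxels.
* NGTDM neighbourhood means are restricted to the ROI; a voxel with no ROI
  neighbour contributes zero to `s(i)`. The coarseness denominator is
  floored at `1e-12`, so a flat ROI yields `1e12` rather than infinity.
* Zero-variance level distributions take skewness = kurtosis = 0, and GLCM
  correlation of a single-level matrix is 1. Degenerate phantoms must not
  produce non-finite features; a single-voxel ROI, which admits no
  co-occurring pair, is the one case that raises an error instead.
* Histogram "energy" is the second raw moment of the levels, deliberately
  distinct from "uniformity" (the sum of squared probabilities); some
  toolkits conflate the two names.

The texture-matrix builders are written in C++ and are verified exactly
against brute-force R oracles (pair enumeration, line scanning with
`rle()`, flood fill, neighbourhood loops) in the test suite.

### Wavelet subbands

The volume is additionally decomposed by a single-level separable
*undecimated* (stationary) wavelet transform with an orthogonal 8-tap
Daubechies filter, yielding 8 subbands labelled by the per-axis filter
sequence (`LLL` ... `HHH`, x-y-z order). The undecimated form was chosen
because subbands keep the input grid, so the original mask applies without
any resampling or index arithmetic. Filters are scaled by `1 / sqrt(2)` per
axis, which makes the analysis a tight frame with bound 1: the 8 subband
energies sum to the input energy (checked to 1e-6 in the tests), constants
pass through `LLL` unchanged, and every `H` subband annihilates constants.
Each subband is re-quantized to 64 levels independently, since subband
value ranges are unrelated to HU. The full registry is therefore
9 x 47 = 423 named features (`HHL_Histogram_Kurtosis`-style names; no
prefix means the unfiltered image).

## Segmentation-uncertainty screening

Manual tumour delineation is uncertain; features that move when the
contour moves a little are not trustworthy. The package mimics contour
uncertainty by re-segmenting each mask twice: every axial slice
independently draws an action from {expand, erode, keep} (uniform thirds)
and a disk radius from 1-4 pixels, and 2D morphological dilation/erosion
is applied in-plane (no through-plane morphology, since the perturbation
is defined per slice). A slice fully erased by erosion keeps its centroid
voxel so masks stay non-empty. The action stream is counter-based, keyed
by (seed, variant, slice), so results do not depend on evaluation order.
The radius is drawn per slice; drawing it once per mask would be the main
alternative, but per-slice draws produce rougher, more realistic contour
variation.

Features are kept if their ICC across the three segmentations exceeds
0.75. The ICC form is ICC(2,1) - two-way random effects, absolute
agreement, single measurement - because segmentation sets play the role of
raters and "robust" means absolute agreement, not mere consistency.

## Feature selection

Stages run in a fixed order on the training cohort only, and survivor sets
are nested by construction on the radiomics side:

1. **Robustness**: ICC(2,1) > 0.75 across the three segmentations.
2. **Redundancy**: greedy pruning of pairs with |Pearson r| > 0.75. The
   member of the worst pair with the larger mean absolute correlation to
   the remaining features is dropped (lexicographic tie-break), making the
   rule deterministic; constant features have undefined correlations,
   treated as zero.
3. **Univariate significance** at alpha = 0.05: Kruskal-Wallis across the
   three subtypes for radiomics features and continuous clinical factors;
   chi-square / continuity-corrected chi-square / Fisher's exact test for
   categorical factors, chosen by the conventional expected-count rule.
4. **Shadow-attribute (Boruta) selection** on the pooled significant
   radiomics features and clinical factors: each iteration shuffles every
   candidate into a "shadow", fits a random forest on originals plus
   shadows, and scores a hit when a feature's permutation importance beats
   the best shadow. Two-sided Binomial(n, 1/2) tests with Bonferroni
   correction confirm or reject features, which then leave the testing
   pool; alpha = 0.01, at most 100 iterations, 300 trees per forest.
   Categorical clinical factors enter integer-coded.

If nothing is significant, the shadow stage is skipped with a notice and
the pipeline reports an empty selection instead of failing - the expected
behaviour under a true null.

## Classifiers

All classifiers consume the selected features; SVM and ANN inputs are
z-scored with training-cohort statistics only (the fitted objects store
those statistics and reuse them at prediction time), trees use raw values.

* **SVM**: one-vs-one soft-margin kernel machines with majority voting
  (kernlab C-svc). Kernels: linear, gaussian, laplacian and ANOVA RBF. The
  laplacian kernel uses the Euclidean distance in the exponent, matching
  the kernel library's definition. The kernel scale defaults to the median
  heuristic on training distances; only the kernel family and the cost
  C in 1..10 are tuned.
* **RF**: bagged trees with `mtry` candidates per split; the OOB error
  trajectory for every tree count up to `n_trees` is retained, which is
  how stabilization with growing forests is assessed (the reference
  configuration is 3000 trees, mtry 2).
* **ANN**: one hidden layer of sigmoid units with softmax output,
  cross-entropy plus L2 weight decay, BFGS optimization from small seeded
  random starts; 5 restarts, best training loss kept. Grid: 10-15 hidden
  units, decay in {2, 1, 0.5, 0.25, 0.125, 0.0625}.

Grid selection uses stratified 4-fold cross-validation (mean
misclassification error for SVM, mean accuracy for ANN) or the OOB error
for RF, with deterministic tie-breaks (smallest C / fewest units and
smallest decay / fewest trees and smallest mtry). CV "mean error" is the
misclassification rate; hinge-type losses are not used.

The cohort is split 70/30 by stratified sampling with per-class
`round(0.7 n_c)` training counts - on class sizes 76/40/48 this gives
exactly 53/28/34.

## Evaluation

Confusion matrices are predicted-by-true. Per class,
precision = TP / row sum, recall = TP / column sum,
F1 = 2PR / (P + R), and overall accuracy = trace / total. Zero
denominators yield 0 with a flag rather than NaN. Display rounding is
half-up to 4 decimals; internal values are never rounded.

## The phantom generator

Each synthetic case is an ellipsoidal tumour (axis-aligned, 20% per-axis
radius jitter) embedded in a textured background. A single white-noise
field over the whole volume is smoothed with an isotropic Gaussian kernel
whose width is the class's `texture_corr_length` (mm), rank-transformed
through a monotone quantile map to the class's target histogram skewness,
discretized to `hist_levels_active` levels (which controls entropy and
uniformity), and scaled to the class HU location/spread. This design
separates the two feature families the screening stage is expected to
recover - texture scale and histogram shape - into independent dials.

The background shares the tumour's discretized texture but with attenuated
contrast and ~20 HU lower enhancement (the tumour enhances in the arterial
phase), and the enhancement difference ramps over a ~2 mm sigmoidal
transition at the contour, mimicking partial volume. Both choices matter
for the robustness screen: a step edge of an alien intensity mode at the
contour - or a continuum of background gray values - would make the 1-4 px
contour perturbations rewrite the ROI histogram, leaving no feature
perturbation-robust, which real CECT tumours (and the screening stage's
expected behaviour) contradict.

The skewness map uses a mirrored-gamma family: a Gamma(k) quantile map has
skewness `2 / sqrt(k)`, so any target magnitude is attainable with
closed-form quantiles in base R, and mirroring handles negative targets; a
skew-normal map was rejected because its skewness saturates near |0.995|,
below the planted values the tests use.

Clinical covariates are drawn class-conditionally for the four informative
factors (log-normal CA 19-9 and CEA, truncated-normal age, Bernoulli sex)
and identically across classes for everything else (tumour location,
diameter, liver enzymes, platelet, albumin, AFP, ferritin, symptom and
history booleans, blood type, obesity defined as BMI >= 25), anchored to
pooled cohort medians (CA 19-9 ~ 10 U/mL, CEA ~ 2 ng/mL, age ~ 55). The
nuisance fields exist to be rejected by the screen. Per-class parameters
are free choices (the source cohort's clinical table pools classes), fixed
once from the clinical picture of the subtypes: MCN almost exclusively
female; IPMN older, more often male, with the highest tumour markers; SCA
predominantly female with low markers. The default class signatures are
deliberately well separated; they define the conditions under which
plant-and-recover assertions are made.

Determinism: a cohort is a pure function of (class sizes, specs, master
seed). Per-case, per-variant and per-slice randomness is derived through a
counter-based Lehmer-LCG seed splitter, so nothing depends on generation
order, and identical seeds reproduce cohorts bit-for-bit.

What the phantom does *not* emulate: pancreas anatomy, contrast kinetics,
CT physics (beam hardening, partial volume, artifacts), inter-rater
segmentation styles beyond expand/erode/keep, or realistic inter-feature
correlation structure. Passing tests therefore demonstrate that the
pipeline recovers planted structure under its own assumptions, not
clinical performance on real CECT.

## Problem sizes and runtime choices

The test suite and the acceptance script run the full pipeline on a
30-per-class cohort with 40 x 40 x 10-voxel volumes, a size at which the
default grids (40 SVM points, 8 RF points, 36 ANN points, 4-fold CV)
complete in a few minutes on one CPU while leaving every stage non-trivial
(ROIs of a few thousand voxels, 423 features, three segmentation sets).
Monte-Carlo assertions use 20 seeded replicates. These sizes are the
package's chosen study conditions for its own verification, not tuning
knobs: thresholds and generator defaults are fixed independently of test
outcomes.

## Known limitations

* The feature registry is fixed at 423 names; shape/morphology and
  filter-bank variants beyond the 8 wavelet subbands are out of scope.
* Fisher's exact test is used for any larger-than-2x2 table with small
  expected counts; mid-p or hybrid rules are not implemented.
* The shadow-attribute selector reports `tentative` for features
  undecided at the iteration cap rather than forcing a decision.
* Kernel scale tuning is by the median heuristic only; per-kernel scale
  grids are not searched, mirroring a workflow that tunes only kernel
  family and cost.
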