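---
title: "Methods: simulating and evaluating TBP lesion triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating TBP lesion triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbptriage)
```

## The problem

3D total-body photography (TBP) captures every visible lesion on a patient
as a small standardized crop (a 15 x 15 mm *tile*) together with
vendor-computed appearance measurements. In surveillance populations a
patient routinely carries hundreds of lesions while only ~1 in 1,000 lesions
is malignant, so the clinically relevant question is not per-lesion
diagnosis but *triage*: rank all lesions so that a small review budget
captures nearly all cancers. `tbptriage` provides the pieces needed to study
this setting end to end: a cohort simulator, pixel-based lesion
measurements, patient-contextual features, baseline and boosted risk models
under a feature-class ablation design, and triage-oriented metrics.

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture. It emulates the
statistical structure that the downstream analysis relies on:

* **Patients cluster by hospital.** Nine centers with unequal weights
  (defaults: 18.9% to 1.2% of patients) and a per-center propensity for
  cross-polarized vs white-light capture. White light attenuates the
  realized lesion/background contrast by a factor of 0.6, reflecting that
  pigmented lesions are easier to see under cross-polarization.
* **Per-patient lesion counts** follow five strata (`<100` ... `400+`) with
  default weights 22.8/18.9/15.3/10.9/32.1%. Within the open-ended top
  stratum, counts are 400 plus an exponential tail (mean 473, capped at
  3,000), chosen so the cohort-wide mean (~400 lesions/patient) and upper
  quartile (~490) match the calibration cohort of 935 patients and 370,704
  lesions.
* **Malignancy** is Bernoulli at 0.09% prevalence by default, with
  melanoma/BCC/SCC subclass proportions 99:190:53 among positives and a
  benign mix dominated by unbiopsied lesions.
* **Appearance traits** (diameter, CIELAB hue, contrast, border
  irregularity, asymmetry, internal color variance) are latent-Gaussian or
  logistic-Gaussian draws; under the default `trait_shift` rule malignant
  lesions are shifted by configurable effect sizes (defaults ~0.6-1.0 SD,
  hue shifted toward red). Ages are uniform on 20-90 in 5-year bins and sex
  is Bernoulli(1/2): no population tables for these are available to
  calibrate against, and nothing downstream depends on their shape.
* **Vendor-style measurement columns** (`tbp_lv_*`) are computed
  analytically from the true traits with 5% relative noise, standing in for
  proprietary measurement software. They are monotone in the traits by
  construction.

A second labeling rule, `malignancy_rule = "relative_size"`, defines
malignancy by a lesion's size *relative to the patient's own lesions*
(within-patient z plus noise exceeding a prevalence-matched threshold, with
per-patient typical sizes spread widely, SD 0.6 on the log scale). Absolute
appearance then carries little class signal while patient context carries
most of it. This construction is the oracle for the context-effect
experiment below.

Determinism: all draws derive from one master seed; each lesion also gets a
`render_seed` hashed from the master seed and lesion index, so tiles can be
rendered for any subset, in any order, with identical output.

**What the simulator does not emulate:** real skin texture, hair and
artifacts, 3D body geometry and occlusion, center-specific phenotype
differences beyond lighting, and any correlation structure among traits
beyond what the shared latent class induces. Tests that pass on this
simulator therefore establish the *mechanics* of the pipeline (correct
formulas, no leakage, monotone recovery), not clinical performance on real
TBP data.

## Tile rendering and pixel measurements

Tiles are rendered at 15/128 mm/px (128 px tiles) by default: small enough
for desk-scale experiments while keeping typical lesions tens of pixels
across. The lesion boundary is the polar curve
$r(\theta) = R\,(1 + \mathrm{irr}\sum_{k=2}^{6} a_k \cos(k\theta+\phi_k))$,
anisotropically scaled by $(1 \pm 0.35\,\mathrm{asym})$ at a random
orientation. Harmonic amplitude *magnitudes* are deterministic in the
irregularity trait (signs, phases, and a +/-15% jitter are random): an early
design with fully random amplitudes made measured jaggedness respond too
noisily to the trait, defeating the generator's purpose of monotone,
independent control of each measured shape feature.

The measurement module fixes concrete, documented stand-ins for proprietary
measurement definitions. All are monotone in the visual property they name;
none claims numerical equality with vendor output:

* **Segmentation**: Otsu threshold on CIELAB L\*, keep the connected
  component containing the tile center, fill holes. Near-uniform tiles
  (L\* range < 1) return "no lesion", and all measurements are reported
  absent, never imputed.
* **Perimeter**: 8-connected boundary walk with Vossepoel-Smeulders step
  weights (0.980 axial, 1.406 diagonal). Raw (1, sqrt 2) chain lengths
  overestimate smooth perimeters by ~5%, which would bias the isoperimetric
  jaggedness $P / (2\sqrt{\pi A})$ of a perfect disc to ~1.05 instead of
  its defining value 1.
* **Minimum lesion diameter**: minimum Feret (caliper) width over a
  1-degree angle grid, plus one pixel of pixel extent. This is exact for
  discs, ellipses and rectangles, unlike the second-moment-ellipse minor
  axis (which is 1.155x the true width of a rectangle).
* **Shape asymmetry**: minimum over a 1-degree grid of axis angles through
  the centroid of the XOR area between the mask and its reflection, divided
  by twice the area; ties broken toward the smallest angle.
* **Color**: sRGB -> CIELAB (D65) via `grDevices::convertColor`, validated
  against independently coded textbook formulas to 0.5 L\*a\*b\* units. Hue
  is the angle of the region-mean chroma vector, reported absent (NA) for
  achromatic regions. The background region is the complement of a 2-px
  mask dilation, avoiding boundary color mixing. Color asymmetry is the
  Delta-E between the mean colors of the two halves split by the
  shape-asymmetry axis.

## Patient context

For every measurement, each lesion gets a within-patient z-score (sample
SD; singletons and zero-variance cases map to 0 so sparse patients do not
flood the model with missing values), a ratio to the patient mean, and a
within-patient percentile (rank/n, ties averaged). Two summary features are
added: the patient's lesion count and an ugly-duckling index — the
Euclidean norm of the lesion's MAD-standardized deviations from the
patient's median measurement vector (zero-MAD components contribute 0). A
lesion identical to the patient median scores exactly 0. All computations
are strictly within patient; tests assert order-invariance and the absence
of cross-patient leakage.

## Risk models

**Baseline.** A multivariable logistic regression on exactly eleven
morphology measurements (area, jaggedness, the three CIELAB channel
contrasts, overall color contrast, minimum diameter, internal color
variation, color asymmetry, background lightness variance, asymmetry angle)
plus the five anatomic-site categories (one-hot, head/neck reference).
Coefficients can be replaced wholesale from a configuration vector, since
the externally published model's coefficients are not printed anywhere and
users may want to plug in their own.

**Boosted model.** Ten ablation variants combine four feature classes:
basic demographics, appearance metadata, image-derived (tile) measurements,
and patient context — the five base combinations each with/without
context. The "tiles" class is realized as the pixel measurements of the
previous section computed directly from rendered images; a GPU-scale neural
image ensemble is deliberately out of scope, and what the ablation needs is
an image-derived signal distinct from the provided metadata. Context
features follow the enabled measurement source (appearance metadata when
present, otherwise the tile-derived block), so no variant sees features
computed from a class it excludes.

Fitting uses 5-fold cross-validation grouped by patient (a patient never
spans a fold's train/validation split). Each fold trains three gradient
boosting tree members that differ by seed and row-subsampling fraction
(0.7/0.8/0.9) — how the members of such ensembles should differ is not
prescribed anywhere, so the package makes a simple choice and exposes it.
Scores are member means; evaluation uses out-of-fold scores. The boosting
depth is chosen per fold from a small grid (3 vs 5) by validation partial
AUC above the 80% TPR floor. The ~0.1% prevalence is handled by per-fold
positive upweighting (negatives/positives). Defaults (eta 0.3, 80 rounds)
favor robustness at desk scale over leaderboard tuning.

## Triage metrics

* **pAUC above 80% TPR**: raw (non-standardized) area between the empirical
  ROC curve and the TPR = 0.8 floor, range [0, 0.2]; tied scores merge into
  single threshold steps, making the curve piecewise linear and the metric
  order-independent. A perfect ranking gives exactly 0.2; an uninformative
  one gives 0.02.
* **AUC**: Mann-Whitney with ties counted half.
* **NNT at x% sensitivity**: lesions triaged per detected malignancy at the
  *fewest-lesions-triaged* threshold whose sensitivity reaches the target
  (the most conservative qualifying cutoff; when ties make the exact target
  unattainable the nearest attainable sensitivity above it is used and
  flagged in the attributes).
* **SE_top-15**: sensitivity when only each patient's 15 top-scoring
  lesions are reviewed, weighting diseased patients equally. Whether this
  should mean "patient detected" or "fraction of the patient's malignancies
  captured" is genuinely ambiguous, so both modes are implemented
  (`"patient"`, the default, and `"macro"`); ties at rank k break by
  descending score then lexicographic lesion id.
* **Per-patient percentiles**: each malignancy's ascending within-patient
  percentile (max rank for ties) and the count of strictly higher-scoring
  lesions, aggregated into the fraction ranked first, at or above the 99th
  percentile, below the 95th, and the median/mean number of outscoring
  lesions.
* **DeLong**: placement-value covariance estimate with a normal
  approximation, p = 1 by convention when the AUC-difference variance is
  numerically zero (identical or monotone-related scores).
* **Association**: per-model ascending rank transform (ties averaged), mean
  rank per lesion, Spearman correlation against continuous features, and a
  two-sample Kolmogorov-Smirnov comparison of subclass score distributions.
  The number of aggregated models is whatever score matrix the user
  supplies; this package aggregates its own variants and seeds.

## Worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n_patients = 12,
                     lesion_count_distribution = c("<100" = 1, "100-199" = 0,
                                                   "200-299" = 0,
                                                   "300-399" = 0, "400+" = 0),
                     malignancy_prevalence = 0.08, seed = 11)
cohort <- generate_cohort(cfg)
report <- run_ablation_study(cohort, cv_seed = 2,
                             model_args = list(nrounds = 15))
print(report)
```

## Problem sizes and numerical choices

The test-suite experiments are sized for a single CPU: pipeline tests use
hundreds of lesions with tile rendering; metric oracles run on 1,000
exhaustively checked instances of up to 20 lesions; the prevalence-recovery
check generates >100k lesions (metadata only, no rendering); the
measurement-recovery sweep uses 200 noise-free tiles; and the
context-effect experiment uses 20 replicate cohorts of ~50,000 lesions at
2% prevalence under the `relative_size` rule, comparing the
appearance+context variant against appearance alone with 50 boosting rounds
at depth 4. The 2% prevalence for this experiment (vs the 0.09% default) is
a power choice: it yields ~1,000 positives per replicate so that the AUC
difference, not Monte-Carlo noise, dominates the comparison.

Degenerate inputs are handled explicitly rather than silently: single-class
label vectors, empty masks, lesions filling the whole tile, achromatic
regions, constant features, and missing measurements each either raise a
named error or propagate an explicit NA.

## Limitations

Measured shape/color values are stand-ins; models trained on them will not
transfer to vendor measurements without recalibration. The simulator's
independence assumptions (traits conditionally independent given class,
sites independent of traits) make the synthetic task easier than real
triage; absolute metric values from synthetic runs should be read as
mechanism checks, not clinical estimates. The image branch is a fixed
measurement extractor, so "tiles vs metadata" comparisons here probe
information content of the rendered pixels only, not representation
learning.
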