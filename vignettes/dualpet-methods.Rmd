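---
title: "Concordance-aware dual-tracer PET quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concordance-aware dual-tracer PET quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients with relapsed/refractory multiple myeloma considered for
CXCR4-directed radiopharmaceutical therapy are imaged with two PET tracers:
a glucose-metabolism tracer (FDG) that marks vital, glycolytically active
disease, and a CXCR4-directed tracer that marks the therapeutic target's
expression. A lesion visible on both scans — with substantially overlapping
segmentations — carries different biological meaning than a lesion visible
on only one. `dualpet` implements a lesion-level quantification pipeline
that makes this concordance explicit, aggregates lesion metrics into
patient-level features stratified by tracer, anatomic site and concordance,
and carries those features through a univariate statistical program and
interpretable decision-tree models.

Because clinical dual-tracer cohorts are small and rarely shareable, the
package ships a synthetic phantom-cohort generator with planted ground
truth, so every stage — segmentation bookkeeping, adjudication, feature
extraction, statistics, attribution — is testable end to end without any
patient data.

## Lesion extraction and concordance adjudication

Lesions are connected components of a binary mask under 26-connectivity
(voxels sharing a face, edge or corner; the standard choice for blob-like
PET uptake; 6-connectivity is available). Each lesion carries its voxel
list, volume (voxel count x voxel volume, ml) and intensity-unweighted
centroid in physical mm.

Two lesions from different tracers are *matched* when their masks share at
least one voxel on the common grid (each tracer is quantified on its own
PET grid; for overlap the CXCR4 mask is propagated to the FDG grid by
nearest-neighbor resampling). A lesion is **concordant** when at least one
of its cross-tracer pairs has volumetric overlap *strictly above* 10%:

> overlap fraction = |A ∩ B| / min(|A|, |B|)

The denominator is a design choice the source convention leaves open; the
minimum volume is the default because it is symmetric under tracer swap and
robust when one tracer's segmentation is much larger, and `a`, `b` and
`union` are exposed as config options. Matching is many-to-many: concordance
is a per-lesion property and no one-to-one assignment is forced. For cohort
totals, a concordant lesion and its partner(s) count as **one** lesion —
concordant units are connected components of the qualifying-pair graph — so
concordant + FDG-only + CXCR4-only exactly partitions the unique lesion
count.

A lesion is **medullary** when at least 10% (inclusive) of its voxels lie
in the bone mask, extramedullary otherwise; the different strictness of the
two 10% rules (strict for concordance, inclusive for bone) follows the
source conventions and both are configurable. A lesion intersecting the
spleen mask by one or more voxels is flagged splenic and excluded from the
spleen reference uptake.

## Patient-level features

Per lesion: SUVmean, SUVmax, MTV (ml), and the burden product
MTV x SUVmean — TLG on FDG, TLC on the CXCR4 tracer. Aggregation to the
patient level runs over the eight strata (2 tracers x medullary /
extramedullary x concordant / discordant), named in bracket notation, e.g.
`SUVmean[FDG medullary concordant]`:

* SUVmean: voxel-pooled (volume-weighted) mean — equal to the mean over the
  union region of the stratum. A mean-of-lesion-means variant exists
  (`pooled = FALSE`); pooled is the default because it is the mean of the
  actual uptake distribution rather than of per-lesion summaries.
* SUVmax: maximum over the stratum; MTV, TLG, TLC: sums.
* Empty strata: burden metrics are 0 (absence of burden is information),
  intensity metrics are missing (an SUV of a nonexistent region is not 0).
  This keeps Welch comparisons well defined without inventing values.

`sDmax` is the maximum pairwise distance between lesion centroids (cm)
divided by body surface area (DuBois–DuBois,
`0.007184 * h^0.725 * w^0.425` m²; Mosteller optional), in cm/m². Centroid
endpoints (rather than surface points) are the default: reproducible, cheap
and insensitive to segmentation-boundary noise. With fewer than two lesions
the distance is undefined and reported missing.

## Statistical program

* **Response**: Welch's unequal-variance t-test per continuous feature
  (two-sided, mean-difference CI) plus Hedges' g, the bias-corrected
  standardized mean difference, with a normal-approximation CI
  (`SE² = (nx+ny)/(nx·ny) + g²/(2(nx+ny−2))`). Binary covariates use the
  chi-square test without continuity correction, switching to Fisher's
  exact test when any expected cell is below 5; odds ratios use the
  Haldane–Anscombe +0.5 correction on zero cells and the Woolf logit CI.
* **Survival**: each feature is dichotomized at the cohort median (ties go
  low), groups are compared with Kaplan–Meier curves (Greenwood variance,
  log-transformed 95% bands clipped to [0, 1]) and the log-rank test, and
  the hazard ratio is approximated by the event-rate ratio
  `(d_high/T_high)/(d_low/T_low)` with person-time denominators (an
  event-proportion variant is available), CI
  `exp(log HR ± 1.96·√(1/d₁+1/d₂))`.
* Missing features are handled complete-case per feature with counts
  reported; no multiple-comparison correction is applied and p-values are
  reported as descriptive, matching the exploratory design of the analyses
  this package supports.

## Decision trees and SHAP attribution

Both endpoints — therapy response, and survival dichotomized at 183 days
(units censored alive before the horizon are excluded and counted) — are
modeled with CART-style binary classification trees (Gini impurity, grown
deep, cost-complexity pruned at the complexity minimizing rpart's inner-CV
error; ties resolve toward the smaller tree; a one-SE rule and a complexity
floor are available for stronger pruning). Missing values route to the
majority child; no surrogate splits.

Model assessment uses repeated stratified 5-fold cross-validation with 10
repeats. Feature attribution uses **exact single-tree SHAP** with the
path-dependent value function: the payoff of a feature coalition S is the
tree traversal that follows the sample for splits on features in S and
averages both children with training-cover weights otherwise. Because a
tree of depth d uses at most 2^d − 1 distinct features, the Shapley sum is
enumerated exactly over the used features (unused features are null players
and receive exactly zero); efficiency of the Shapley value gives the local
accuracy identity `base + Σφ = p̂` to machine precision.

Attributions are computed on the *validation* fold (a config switch allows
training-fold attribution) and aggregated as the mean of |SHAP| over all
validation samples pooled across folds and repeats. Directionality is made
testable as: each fold votes the sign of the within-fold Pearson
correlation between feature value and attribution (folds with constant
attribution abstain); `sign_agreement` is the fraction of voting folds
matching the modal direction, with ≥ 0.80 flagged stable.

## The synthetic cohort generator

The generator emulates the study conditions of a 22-patient dual-tracer
cohort; one treatment cycle per patient is emitted (unit = row).

* Lesion counts per patient: uniform on 20–109 (median 64.5).
* Per-patient concordant fraction: Beta with mean 0.40, concentration 5
  (spreading patients over roughly 5–90% concordance); likewise the
  extramedullary fraction (mean 0.40). Discordant lesions are FDG-only
  with probability 0.206 (one FDG-only per ~3.9 CXCR4-only).
* Anatomy: ellipsoidal body, box spine + cylindrical femurs as bone, a
  small ellipsoidal spleen — minimal geometry sufficient for the site and
  spleen rules.
* Lesions are spheres (radius uniform on 3–6 mm) with uniform uptake at a
  lognormal peak SUV per tracer and class on a background of SUV 1.0; a
  Gaussian-tapered profile is optional. Spheres make MTV/TLG analytic, so
  ground-truth features are computed from the continuous geometry,
  independent of voxelization. Concordant lesions are planted at the same
  center in both tracers with independently jittered radii
  (lognormal sd 0.12); discordant lesions appear in exactly one tracer.
  Centers are rejection-sampled with a pairwise separation of the two
  radii plus twice the voxel pitch, so distinct lesions can never merge
  under 26-connectivity.
* Outcomes are generated from the *planted* features (never from
  re-extracted ones, so extraction error stays separately measurable):
  response ~ Bernoulli(logistic(β·z)), survival ~ exponential with hazard
  h₀·exp(β·z) (default h₀ = log 2 / 198 per day, i.e. a 198-day median at
  baseline) and independent exponential censoring calibrated to a target
  marginal censoring probability.
* Determinism: all randomness is drawn in the planning phase, so
  `render = FALSE` (no voxel painting) yields bit-identical plans and
  outcomes; identical configs give bit-identical cohorts.

What the generator does **not** emulate: PET noise and point-spread
blurring, reconstruction artifacts, scanner harmonization differences,
irregular lesion shapes, deformable anatomy, or correlated lesion/SUV
distributions within patients (the source reports only marginal medians
and ranges). Passing recovery tests therefore demonstrates correctness of
the pipeline's bookkeeping and statistics under known truth — not
robustness to real-world image degradation.

## Numerical choices and degenerate inputs

* Physical convention: voxel (i,j,k) (1-based) has center
  `origin + (index−1)·spacing` mm; all geometry in mm, volumes in ml.
  Oblique NIfTI affines are rejected, not silently reoriented.
* A planted sphere whose radius captures no voxel center degenerates to
  the single voxel containing the center.
* Identical constant samples in the Welch test return the exact null
  (t = 0, p = 1, g = 0) rather than 0/0.
* Zero event counts get +0.5 continuity in the event-rate HR (with a
  warning); zero cells get +0.5 in odds ratios.
* Median splits send ties low; a constant feature produces an empty high
  group and a warning, and is skipped by the batch analyzers.
* Constant features are never selected by the tree (no impurity gain);
  features absent from all splits receive exactly zero attribution.
* Problem sizes in the test-suite simulations (100 random 20³ phantom
  pairs for oracle equivalence; 200 Welch replicates at n = 200; 100
  survival replicates at n = 300; 50 CV-SHAP generator seeds at n = 150;
  2000 null replicates) were chosen so each suite settles its acceptance
  band comfortably while the full suite stays around a minute.

## Known limitations

* The concordance denominator and the pair-chain counting rule are
  package decisions (exposed in config); other conventions would change
  lesion counts at the margins.
* Event-rate-ratio HRs are crude relative to Cox models (out of scope by
  design) and assume roughly proportional hazards over follow-up.
* The SHAP direction vote is a linear summary of a potentially non-linear
  attribution–value relationship; it mirrors how summary plots are read,
  but can abstain or mislead for non-monotone effects.
* Exact SHAP enumeration is limited to trees using ≤ 15 distinct features
  (2^15 coalitions); far above any depth-limited tree this package fits.
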