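---
title: "CT body composition and sarcopenia prognosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT body composition and sarcopenia prognosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsarco)
```

## What the package computes

`ctsarco` quantifies body composition on CT volumes and evaluates its
prognostic value on survival cohorts. The measurement side has two routes,
both driven by Hounsfield-unit (HU) classification:

* **Single-slice L3 anthropometry.** Skeletal muscle, visceral-fat and
  subcutaneous-fat cross-sectional areas are measured on two adjacent axial
  slices at the third lumbar vertebra and averaged; muscle area divided by
  height squared gives the skeletal muscle index (SMI, cm²/m²), classified
  against the Prado sex-specific cut-offs (52.4 for men, 38.5 for women,
  strict `<`). L3 areas are the standard single-slice surrogate for
  whole-body composition.
* **Multi-slice body-composition measurement.** All voxels between the
  eyes and ischia landmarks (the usual PET/CT acquisition window) are
  classified within three masks — body shape, abdominal cavity, muscle
  compartment — and converted to masses by `mass = N · V_voxel · ρ` with
  ρ = 1.06 g/ml for muscle and 0.923 g/ml for fat. Body parts outside the
  window are recovered with extrapolation factors `k_muscle` and `k_fat`,
  each the mean ratio of whole-body to in-window tissue voxels over a set
  of whole-body reference volumes. Estimates are reported as masses (kg)
  and height-normalized indices (kg/m²): muscle (MBM), fat (FBM), lean
  (LBM), visceral-fat (VFM) and subcutaneous-fat (SCFM) body mass.

The statistical side reproduces the classical prognostic workflow for such
markers: nutritional indices (BMI, signed weight-loss %, Buzby NRI),
two-group comparisons, Kaplan–Meier curves with log-rank tests, ROC-based
optimal dichotomization, univariate Cox models (continuous and
dichotomized), and stepwise multivariate Cox selection.

## HU classification model

Tissue classes are defined by inclusive integer HU bands: fat is
−190 … −30, skeletal muscle −29 … +150. With integer HU the two bands are
adjacent and disjoint, so the classification is a partition. The masks
resolve the remaining ambiguity:

* fat-range HU inside the abdominal cavity → visceral fat;
* fat-range HU inside the body but outside the cavity → subcutaneous fat
  (including intramuscular fat inside the muscle compartment — HU wins
  over location);
* muscle-range HU counts as skeletal muscle only inside the muscle
  compartment; the same HU elsewhere in the body is "other" (organs);
* outside the body mask everything is background, whatever its HU.

Lean body mass is not given a definition by the clinical convention this
workflow follows, so the package defines it explicitly: in-body, in-window
voxels with HU ≥ −29 (non-fat, non-air), massed at muscle density and
extrapolated with `k_muscle`. This is an interpretation and is documented
as such on `compute_body_composition()`.

VFM is deliberately **not** extrapolated: the abdominal cavity lies inside
the eyes–ischia window, so out-of-window fat is subcutaneous by
construction, and `SCFM = FBM − VFM` absorbs the extrapolated remainder.
FBM is assembled as `VFM + SCFM` at every reported level so that the
conservation identity holds to the last floating-point bit.

## The phantom generator

Real multi-atlas segmentation and a clinical cohort are not reproducible at
desk scale, so the package ships a first-class phantom generator with
analytically known ground truth. A phantom is a stack of nested elliptic
cylinders (outside→in: air, subcutaneous fat shell, muscle ring, core with
an abdominal cavity of visceral fat mixed with organ tissue, and a central
bone column). Each voxel carries a ground-truth label; truth masses follow
the same `N · V_voxel · ρ` rule, so measured masses can be compared with
exact references.

Default conditions (all overridable in `phantom_spec()`):

| parameter | default | rationale |
|---|---|---|
| grid | 256 slices × 128 × 128 | torso-scale volume that still runs in seconds |
| spacing | (2, 3, 3) mm | 2 mm slice thickness, the acquisition convention this workflow targets |
| body semi-axes | 170 × 110 mm | adult torso cross-section |
| fat shell / muscle ring | 15 / 12 mm | plausible subcutaneous and muscular thickness |
| landmarks | eyes 26, L3 140, ischia 204 | head ≈ 10% and sub-ischial ≈ 20% of slices outside the window |
| HU means (air/fat/muscle/organ/bone) | −1000 / −100 / +40 / +55 / +700 | textbook tissue attenuation |
| HU noise SD | 10 | keeps fat and muscle ≥ 6σ inside their bands; generation validates ≥ 99% band purity and errors otherwise |

HU are stored as integers (CT convention); Gaussian noise is rounded. One
seed drives deterministic per-compartment sub-streams, so generation is
bit-reproducible.

The per-slice `profile` scales the body cross-section (0.55 above the eyes,
1.0 through the trunk, 0.8 below the ischia by default) so that
out-of-window tissue actually exists and `k > 1`. For shell-like tissues
(muscle ring, fat shell) the whole-body/in-window ratio depends only on the
profile, not on overall body size, which is why factors calibrated on a
"family" of phantoms sharing the profile transfer across sizes; the
visceral component scales with area rather than perimeter, which introduces
the small size-dependence visible in `k_fat` across a scaled family.

**What the phantom does not emulate:** anatomy (no organs with distinct
shapes, no limbs separate from the torso, no partial-volume voxels at
tissue interfaces, no beam-hardening or metal artifacts), inter-patient
variability in band overlap (real intramuscular fat infiltration shifts
muscle HU down into the band edge), and PET content. Passing the phantom
recovery tests therefore demonstrates that the counting, mass and
extrapolation arithmetic is correct — not that the HU bands segment real
patients accurately, which is a property of the bands themselves, taken
here as fixed inputs from the field's convention.

Indexing convention: slice 1 is the most cranial; landmark indices are
1-based and slice ranges inclusive (`eyes:ischia`), matching R idiom.

## The cohort simulator

`simulate_cohort()` draws event times from a proportional-hazards
exponential model `T ~ Exp(λ₀ · exp(Σβx))` with administrative and/or
random censoring, over generated demographics (sex, height, weight, usual
weight, albumin with configurable missingness, WHO score) plus arbitrary
continuous/binary markers with planted log-hazard-ratios. Defaults echo a
radiochemotherapy NSCLC cohort scale: n is user-set, 78.5% male, median
weight ≈ 70 kg, albumin ≈ 37 g/L, baseline median survival 24 months.
Planted-effect recovery tests use n = 500–1000, HR = 2 on a balanced
binary covariate and administrative censoring at 36 months (≈ 20–25%
censored), which are the conditions the validation suite runs under.

The simulator is intentionally simpler than a real cohort: no correlation
between covariates, exponential (constant) baseline hazard, independent
censoring. That suffices for validating estimator calibration (CI coverage,
parameter recovery) but says nothing about robustness to non-proportional
hazards, which the package does not address.

## Statistical procedures and numerical choices

* **Kaplan–Meier / log-rank / Cox** delegate to the `survival` package.
  The KM median is the smallest observed time with S(t) ≤ 0.5 (NA if never
  reached); median follow-up uses reverse KM. Cox models use the Breslow
  tie approximation — the most common default, stated here because the
  choice affects tied event times.
* **Dichotomization** of a marker at threshold `t` produces the indicator
  `value < t`, so the at-risk (low-marker) group is coded 1 and HR > 1
  means low values are adverse.
* **ROC.** AUC by the rank/Mann–Whitney construction, oriented so that a
  low marker predicts the adverse outcome. One-sided p for AUC > 0.5 via
  the tie-corrected normal approximation; below 30 observations without
  ties the exact Mann–Whitney null distribution (the permutation
  distribution of the AUC) is used. A threshold is emitted only when
  AUC > 0.5 at α = 0.05. "Simultaneously maximizing sensitivity and
  specificity" is implemented as maximizing Youden's J = sens + spec − 1
  over the midpoints of adjacent sorted unique marker values — an
  exhaustive search, since no other cut changes any classification. Ties
  in J break toward the lower threshold (more patients flagged at-risk
  when low is adverse); a closest-to-(0,1) rule is available via
  `rule = "closest01"`. The ROC outcome is vital status at end of
  follow-up; conflating a time-to-event outcome with a binary one is a
  recognized weakness of this clinical convention, inherited knowingly.
* **Two-group comparisons.** Qualitative: χ² without continuity
  correction (the plain Σ(O−E)²/E), switching to Fisher's exact test when
  any expected cell is < 5. Quantitative: Student's t (equal variances)
  when both groups pass Shapiro–Wilk at α = 0.05, else
  Wilcoxon–Mann–Whitney. The normality gate is a package decision — the
  clinical convention names both tests without a rule.
* **Stepwise Cox selection.** Candidates with > 25% missing values are
  excluded and reported; the rest are screened by univariate Cox
  (likelihood-ratio p < 0.05), then forward–backward selection on the
  partial likelihood with p_enter = p_remove = 0.05. Ties break by
  smallest p, then name order, so the procedure is deterministic.
  Perfectly collinear covariates cannot both enter: the second adds no
  identifiable parameter, so its entry p is 1 by definition. Note the
  family-wise property of α = 0.05 entry: with five independent noise
  candidates, the chance that at least one enters alongside a true effect
  is roughly 1 − (1 − q)⁵ with q ≈ 0.03 the joint screen-and-enter
  false-positive rate, i.e. an expected "clean model" rate near 85–87%,
  not 95%. This is inherent to p-value-driven stepwise selection, not an
  implementation artifact.
* **NRI** uses the Buzby formula `1.519 · albumin (g/L) + 41.7 ·
  (weight / usual weight)`; weight loss is signed
  (`100 · (weight − usual)/usual`, negative = loss); at-risk flags at
  BMI < 21, albumin < 35 g/L, NRI < 97.5.

## Problem sizes in the validation suite

The test suite and `scripts/acceptance.R` run at sizes chosen to exercise
every code path while staying desk-scale: one full-size default phantom
(256×128×128) for untruncated mass recovery; a half-resolution
(128×64×64) three-phantom family scaled ×0.95/1.00/1.05 for extrapolation
calibration and recovery; 200 simulated cohorts of n = 500 for Cox
calibration; 100 replicates for stepwise selection and for ROC brute-force
equivalence (n ≤ 200 per instance); and an exhaustive integer HU sweep
−1100…1100 for band boundaries. Oracles are independent implementations:
nested-loop voxel membership and counting, hand-computed product-limit and
observed-expected tables, exhaustive hypergeometric enumeration for
Fisher's test, and exhaustive cut enumeration for ROC thresholds.

## Known limitations

* Masks come from phantom geometry or user files; multi-atlas registration
  (how masks are produced clinically) is out of scope, so segmentation
  quality on real CTs is untested here.
* L3 localization is an input (landmark or index), not detected.
* The phantom's band purity makes classification near-perfect by design;
  real tissue HU distributions overlap at band edges.
* Proportional hazards and independent censoring are assumed throughout;
  no competing risks, time-varying covariates, or multiplicity correction
  across univariate screens (deliberately mirroring common clinical
  practice).
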