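---
title: "Models and design choices in claustrumdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in claustrumdev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claustrumdev)
```

`claustrumdev` analyses claustrum structure in neonatal brain MRI: ROI
outcomes from a parcellation label volume plus co-registered diffusion
maps, cross-sectional and longitudinal group statistics, and structural
covariance networks. Because the neonatal imaging data it targets are
access-gated, the package ships a synthetic generator that emulates the
study design, and validates every stage by parameter recovery. This
vignette documents the models, the parameters that matter, and the
places where the design was genuinely open.

## ROI outcomes and the two control masks

A `label_volume` is an integer grid with voxel sizes in mm and a
`label_scheme` mapping ids to region names and tissue classes. All
morphology is done in voxel index space, on 0-based logic with
zero-padded boundaries; the affine is carried only for NIfTI I/O.
Anisotropic voxel sizes are deliberately ignored by the structuring
elements — the operators are defined on indices, which keeps them
reproducible and testable against brute-force oracles.

* **Absolute volume**: voxel count × voxel volume.
* **Total brain volume (TBV)**: all labels except background, CSF and
  ventricles; the brainstem is included.
* **Relative volume**: per side, side/TBV; combined, (left + right)/TBV.
  Other outcomes (volume, MD, FA) combine sides as the arithmetic mean.
* **ROI means**: arithmetic mean of the metric at mask voxels; an empty
  mask yields a missing value, never zero. FA is clipped to [0, 1] at
  ingest with a recorded count; MD is fixed at 10⁻³ mm²/s at the I/O
  boundary.

Two control masks delimit the thin claustrum sheet from its
surroundings:

* The **claustrum frame** — "augmented by around two voxels on all
  sides" is implemented as a Chebyshev ball of radius 2 (two iterations
  of 3×3×3 dilation), intersected with insular white matter, minus the
  claustrum. The Chebyshev reading is the most literal "all sides"
  interpretation and the simplest reproducible one; the radius is a
  parameter.
* The **claustrum-controlled** mask — voxels "surrounded by at least
  90 %" claustrum are read strictly: the fraction of the
  26-neighbourhood (centre excluded, out-of-bounds counted as
  non-claustrum, same side only), so the default requires ≥ 24 of 26
  neighbours. Whether the original criterion used a 26-neighbourhood or
  a larger sphere is not stated anywhere we could find, so both the
  connectivity and the fraction are exposed as parameters rather than
  guessed; `fraction = 1` is the strictest nested special case.

Every extraction asserts controlled ⊆ claustrum, frame ∩ claustrum = ∅
and frame ⊆ insular WM. Diffusion maps are assumed already resampled to
label space; a shape/voxel-size compatibility check is mandatory and
resampling is intentionally out of scope.

## Group statistics

`fit_glm()` is ordinary least squares with the group coded term = 0 /
preterm = 1 and sex female = 0 / male = 1. Effect sizes are partial
η² = t²/(t² + df) per 1-df term, equivalent to SS_term/(SS_term +
SS_resid). The formula behind published partial η² values is rarely
printed; this is the standard choice and reproduces the published
values in recovery simulations (below). Sums-of-squares type is
irrelevant here because every model has a single categorical term plus
continuous covariates. Rows with missing values are dropped per
analysis with a logged count, mirroring the differing structural and
diffusion sample sizes such studies report.

`match_controls()` implements greedy minimal scan-age-gap matching.
Processing order and tie-breaks are not specified in the design it
emulates, so they are fixed deterministically: preterm subjects in
ascending scan age (ties by id); each takes the unused control with the
smallest absolute gap (ties: smaller control scan age, then smaller
id). Output is independent of input row order and never reuses a
control.

`fit_random_intercept_model()` wraps `lme4::lmer` (REML) with a single
random intercept per subject. Fixed-effect p-values are Wald tests
against the standard normal — a documented approximation without
small-sample df correction, adequate at the n ≈ 50–130 of the target
designs.

## Structural covariance

Each region column is correlated with the claustrum column across
subjects (Pearson, pairwise-complete), transformed by Fisher's
z = atanh(r), and compared between groups with the standard
two-independent-sample test Z = (z_PT − z_FT)/√(1/(n_PT−3) +
1/(n_FT−3)). The source analysis names only "tested for significant
differences" after an r-to-z step; the two-sample Fisher z test is the
standard test that the transformation implies, and is the design choice
made here. Sample correlations are clamped to ±(1 − 10⁻⁷) with a
warning before transforming.

The FDR family is all regions within one (metric, side) combination —
the family definition is ambiguous in such designs and is exposed in
the configuration. Benjamini–Hochberg adjustment is order-preserving
with q ≥ p; significance means q < 0.05 by default. Tissue summaries
report mean ± SD of z per class and the "n significant / n total"
convention per class (34 cortical GM, 12 subcortical GM, 33 WM regions
in the default scheme). Correlations are computed on raw metric values
with no covariate residualisation, matching the analysis emulated.

## The synthetic generator

The generator's defaults are the study conditions: group sizes 83/83
(72/72 for diffusion), scan ages 41.1 ± 1.7 GA weeks truncated to the
matched analysis window 37.4–44.9 (term spectrum: 38–45; longitudinal
first/second scans 34.3 ± 1.9 / 41.2 ± 1.5), and per-outcome group
means/SDs and growth slopes taken from the published group tables
(e.g. right claustrum volume 341 ± 51 term vs 363 ± 58 preterm mm³;
slopes 17.1/12.1 mm³ per week; FA 0.216/0.219 term). Covariance levels
default to tanh of the published class-level mean z per group and
metric.

The noise model is Gaussian throughout — the emulated study reports
means ± SDs only, so this is the simplest sufficient model for recovery
testing. Specified SDs are *marginal* within-group SDs: the generator
subtracts the slope-explained variance (computed from the realised
scan-age draw) to get the residual SD, so empirical group SDs match the
specification irrespective of the slope. Scan ages keep their printed
marginal distribution; birth ages are then drawn conditionally below
the scan age (truncated normal, preterm < 37, term 37–42), which
preserves the scan-age equivalence of the two groups that the matched
design relies on. Sex has no generative effect — it is only a
covariate in the emulated analyses.

Unprinted quantities are labelled free defaults and chosen once at
physiologically plausible neonatal levels:

* **Inter-side correlation 0.85** — derived from the printed per-side
  vs combined volume SDs (51/55 per side vs 51 combined; 58/56 vs 55),
  which it reproduces to under 1 mm³.
* **TBV ≈ 356 000/369 000 ± ~48 000 mm³** — implied by the printed
  combined absolute and TBV-relative volumes.
* **Within-subject intercept SD** — no within-subject covariance is
  published for the longitudinal outcomes; the default is a fraction
  0.5 of the marginal SD, with the residual scaled so the
  cross-sectional SD at fixed age is preserved.
* **Control-region levels** (thalamus/caudate volume, GM MD/FA,
  insular/lentiform/frame FA) and phantom tissue MD/FA means and voxel
  noise SDs.

One caveat the recovery tests make explicit: per-side MD means are
published at two decimals (1.08/1.09 vs 1.09/1.10), which rounds the
combined contrast from 0.02 down to 0.01. Recovery simulations of
*combined* outcomes therefore draw directly from the published combined
group values rather than deriving them from per-side draws; default
cohort tables remain internally consistent (combined = mean of sides).

Regional tables use a one-factor construction: with the standardized
claustrum value z_c, a region with target correlation ρ is
mean + sd·(ρ·z_c + √(1−ρ²)·ε). The population region–claustrum
correlation is exactly ρ; region location/scale are free and provably
irrelevant (the analysis is invariant to affine rescaling, and tests
assert this).

The voxel phantom is a geometric stand-in, not a realistic brain: an
ellipsoidal brain with CSF rim, cortical shell, central white matter,
ventricles, three subcortical nuclei, a brainstem cylinder, and one
thin claustrum sheet per side wrapped in an insular WM shell (Chebyshev
radius 3, so the frame operator at radius 2 stays inside it) and an
insular cortex ring. Geometry is deterministic given the spec; seeds
affect only the metric noise fields. Phantom claustrum volumes (~70 mm³
at the default grid) are therefore smaller than real neonatal claustra;
the phantom validates *operators* (mask geometry, means, round-trips),
not volumetric realism. What passing tests consequently do **not**
show: robustness to cortical folding, segmentation error, registration
misalignment, scanner artefacts, or non-Gaussian outcome distributions.

## Numerical and degenerate-input choices

* Morphology uses vectorised array shifts; oracle tests compare against
  triple-loop implementations exhaustively on grids ≤ 16³.
* The controlled-mask threshold compares the neighbour count against
  `fraction · 26 − 1e−9` to keep the ≥ comparison exact at
  representable fractions.
* Empty masks flag missing values; an empty claustrum label is an
  error; an empty frame is a warning (the mask may legitimately vanish
  for very thin sheets).
* Zero-variance paired differences and rank-deficient GLM designs are
  errors that name the offending terms.
* Longitudinal age pairs with second ≤ first are resampled (at most 100
  rounds) before erroring.
* GLM recovery simulations average η̂² over replicates; the estimator
  has the usual small upward noncentrality bias (≈ 1/df), visible as
  recovered values sitting ~0.003 above the population value at
  n = 166. This is inherent to the published estimator, not corrected
  away.

## Problem sizes used in the test-suite simulations

Moment-recovery checks use 2 000 subjects per group; η² recovery uses
200 replicates of the published design sizes (83/83 and 72/72);
covariance recovery uses 50 replicates of 72 subjects × 34 regions;
null calibration of the group test and of the FDR pipeline uses 2 000
replicates each; mixed-model slope recovery uses 200 replicates of 53
subjects × 2 sessions. These sizes make Monte-Carlo error small against
every asserted tolerance while keeping the default test run fast on a
single CPU.

## Known limitations

* No image registration or resampling: inputs must be voxel-aligned.
* No nonlinear age models — the emulated analyses are deliberately
  linear; trajectories over wider age ranges would need spline or GAM
  extensions.
* Wald inference for mixed models and the normal approximation of the
  covariance z test are asymptotic; very small groups (< ~10) should
  use exact or bootstrap alternatives.
* The synthetic cohort draws outcome columns independently across
  outcome families (volumes vs MD vs FA), so cross-metric covariance
  structure is not emulated.
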