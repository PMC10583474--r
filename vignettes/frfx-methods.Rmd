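---
title: "Functional liver remnant estimation from CT texture: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional liver remnant estimation from CT texture: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Before a major hepatectomy, surgeons enlarge the future liver remnant (FLR)
with ALPPS (associating liver partition and portal vein ligation for staged
hepatectomy, days) or portal vein embolisation (PVE, weeks). The anatomic
volume gained is not all working tissue: rapid regeneration, especially after
ALPPS, produces oedema and venous congestion that inflates the remnant on CT
without adding function. A remnant that looks big enough may therefore still
fail, and post-hepatectomy liver failure (PHLF, ISGLS grade >= B) remains the
feared complication.

`frfx` implements a texture-based decomposition of the remnant: functional
parenchyma and oedema/congestion differ in their CT intensity statistics, so
a classifier trained on radiomic features can split the anatomic remnant
volume (FRL) into a functional part (FRFx) and an oedematous rest. The
package covers the whole chain — volumetry, radiomic feature extraction,
feature selection, classification, and cohort-level outcome analysis — plus a
synthetic phantom generator so every stage is testable without patient data.

## Volumetry

All volumes are voxel counts times voxel volume, in cc. With TLV the total
liver volume and TV the tumour volume (both measured on the pre-modulation
study), the package computes

* `FRLV% = FRL / (TLV - TV) x 100` and `FRFxV% = FRFx / (TLV - TV) x 100`,
* `iFRL% = (FRLpost - FRLpre) / FRLpre x 100` (identically `iFRFx%`),
* `BSA = sqrt(height_cm x weight_kg / 3600)` (Mosteller),
* `sFLR = FRL / (-794.41 + 1267.28 x BSA) x 100`, the remnant standardised to
  the BSA-estimated total liver volume,
* `KGR = (FRLV%post - FRLV%pre) / days`, the kinetic growth rate in
  percentage points per day.

Two reporting conventions are fixed here and exposed as options. First, sFLR
is multiplied by 100 so it reads as a percentage, matching how the quantity
is usually tabulated; the denominator is the standardised-TLV regression
estimate. Second, KGR is computed on the FRLV basis by default; a
`kgr_basis = "sflr"` switch computes it on the sFLR basis instead, since both
conventions appear in the surgical literature. The normaliser `TLV - TV` is
taken from the pre-modulation study for both timepoints so that pre and post
percentages share a scale; using a post-study TLV would conflate remnant
growth with whole-organ change.

## The radiomic catalogue

`extract_catalogue()` emits exactly 106 features per region: 19 first-order,
16 shape, 22 GLCM, 16 GLRLM, 16 GLSZM, 12 GLDM and 5 NGTDM. The catalogue
composition is frozen in `inst/extdata/catalogue.json` and versioned; the
families follow the standard radiomics definitions (IBSI-style), with these
numerical conventions:

* **Discretisation.** Fixed bin width of 25 HU anchored at the region
  minimum (`bin = floor((v - min) / 25) + 1`). Fixed-width binning is the
  reproducibility recommendation for CT, where intensities are calibrated;
  entropy and uniformity are computed over this histogram in bits.
* **First order.** Population (1/n) variance; kurtosis on the Fisher+3
  convention; skewness and kurtosis defined as 0 for regions without two
  distinct values; robust MAD over the 10–90 percentile sub-range
  (type-7 quantiles throughout).
* **Texture matrices.** Co-occurrence and run-length matrices are
  accumulated over the 13 unique 3-D directions at distance 1, symmetric
  co-occurrence, features averaged over directions. Zones and dependences
  use the 26-neighbourhood; GLDM dependence is the voxel itself plus its
  equal-level neighbours (alpha = 0).
* **Degenerate regions.** A single-grey-level region returns each family's
  closed-form limit instead of NaN: GLCM correlation is 1 by convention,
  inverse variance 0, NGTDM contrast/busyness 0, coarseness capped at 1e6.
  Each convention is unit-tested.
* **Shape.** Surface area and mesh volume come from a marching-tetrahedra
  triangulation (Kuhn 6-fold cube decomposition) of the 0.5 level-set of the
  Gaussian-smoothed (sigma = 1 voxel) binary mask. Meshing the smoothed
  indicator instead of the raw voxel steps removes the staircase-area
  inflation that would otherwise bias sphericity low; a digitised
  radius-10 ball scores sphericity 0.99 under this scheme. Masks too small
  for the smoothed field to reach the level fall back to the binary field,
  and single-voxel masks are flagged degenerate. Axis lengths derive from
  the eigen-decomposition of the voxel-coordinate covariance; the three
  maximum 2-D diameters are per-plane surface-voxel diameters. The family
  has 16 members; spherical disproportion is omitted as an exact monotone
  transform of sphericity.

Feature matrices are standardised column-wise (z-scores) with parameters
estimated on the training split only; columns constant on the training split
are dropped and recorded.

## The functional-tissue classifier

The spatial unit of classification is a non-overlapping cubic patch of 4^3
voxels (1.0 cc at 2.5 mm spacing) — large enough for stable first-order
statistics, small enough to localise an oedema rim. The chain is:

1. **Harvesting.** Training patches come from cases with known composition:
   pre-modulation FLR parenchyma (functional by definition — before
   modulation there is no hypertrophy) and post-modulation regions labelled
   functional or oedema by the phantom truth masks. Patches must be >= 50%
   inside the vessel-and-tumour-free FLR mask, and labelled patches must be
   >= 90% one class (`purity`); boundary patches are left unlabelled.
2. **Selection.** Information gain (mutual information with the class label,
   equal-frequency 10-bin discretisation, in bits) ranks the first-order
   features; the top 5 (configurable) enter the model. Selection is
   restricted to the first-order family: on congruent cubic patches the
   shape features are constants, and restricting to histogram statistics
   keeps the classifier interpretable as a tissue-intensity profile. Within
   the family, only the 17 *intensive* members are candidates: energy and
   total energy are extensive — they scale with the in-mask voxel count —
   so on variable-coverage patches they encode how much of the cube lies
   inside the parenchyma (boundary geometry) rather than tissue texture,
   which would let a classifier "detect" rim oedema with zero intensity
   contrast. They are still reported in the selection table (flagged as
   non-candidates) and still extracted for whole regions. Ties are broken
   lexicographically by feature name. A pooled-variance t screen
   per feature and an exploratory k-means (k = 2, k-means++ seeding, Lloyd
   iterations, best of 10 restarts) with a Rand index against the truth
   labels are reported alongside; k-means is deliberately a report, not a
   decision stage.
3. **Model.** L2-penalised logistic regression (ridge 1.0 on standardised
   features, intercept unpenalised) fit by Newton iterations to a gradient
   max-norm below 1e-6. Standardisation happens before selection; selecting
   on standardised features makes the information-gain ranking invariant to
   feature scale (it already is, being rank-based) and lets the stored model
   carry one set of per-feature location/scale parameters.
4. **Volume integration.** At prediction time the analysis mask is tiled
   into patches; patches with >= 50% coverage are classified at the 0.5
   probability threshold, and the parenchyma of low-coverage patches
   inherits the nearest classified patch's label, so the classified volume
   always exhausts the analysable parenchyma. `FRFx` is the total volume of
   functional-labelled parenchyma — a hard assignment, which keeps the
   estimate interpretable as a volume of tissue rather than an expectation.

Class imbalance is deliberate: functional patches dominate training (the
whole pre study plus the functional share of post studies), so the fitted
intercept encodes that prevalence. Absent any texture evidence the
classifier therefore defaults to "functional" and FRFx collapses to FRL —
the desired null behaviour, since inventing oedema from noise would bias
FRFxV down. The flip side is that cross-validated accuracy must be read as
*balanced* accuracy (mean per-class recall, `cv_patch_accuracy()`): under
zero contrast a prevalence-driven classifier scores 0.5 balanced accuracy,
the no-information point.

## The phantom generator

The generator produces paired pre/post cases at 64^3 voxels, 2.5 mm
isotropic (voxel = 0.015625 cc): desk-scale volumes on which the full
pipeline runs in fractions of a second. What it emulates, and the defaults:

* **Anatomy.** An ellipsoid-like liver (axis ratios sampled in 0.88–1,
  TLV ~ N(1400, 150) cc truncated to 1100–1650 — the largest ellipsoid that
  fits the grid with margin), an FLR as one side of a plane holding a
  U(0.22, 0.40) fraction of the liver (met to one voxel), a spherical tumour
  (U(30, 120) cc) buried in the deepest part of the non-FLR side, and random
  cylindrical vessels covering ~3% of the liver.
* **Growth.** The post FLR is the pre FLR grown by chamfer-distance dilation
  to `(1 + g)` times its volume, never into the remaining liver or tumour.
  `g ~ Gamma(shape 8)` with mean 1.2 (ALPPS) / 0.7 (PVE).
* **Oedema.** A fraction `theta` of the post-FLR parenchyma, placed as the
  outer rim of the grown region (shallowest erosion depth first, exact to
  one voxel). `theta ~ Beta(concentration 10)` with mean 0.45 (ALPPS) / 0.20
  (PVE). Rim placement is a modelling choice — the spatial pattern of
  congestion is not observable in our inputs — chosen because peripheral,
  spatially coherent congestion is both physiologically plausible (venous,
  subcapsular and transection-surface congestion) and *harder* for a patch
  classifier than salt-and-pepper noise. Concentration 10 gives
  case-to-case theta spreads (sd ~ 0.13–0.16) consistent with the wide
  anatomic-versus-functional gaps seen across reported remnant volumes; the
  Gamma shape 8 likewise reproduces a realistically wide growth spread.
* **Texture.** Each tissue class is `mu + sigma x G`, with `G` unit-variance
  Gaussian-smoothed white noise at correlation length lambda (voxels):
  functional (105, 12, 1.0), oedema (70, 20, 2.0), vessel (180, 10, 0.5),
  tumour (45, 15, 1.5), background (-75, 10, uncorrelated). The 35 HU
  contrast with heavy overlap (oedema patch means spread +-15 HU through the
  long correlation length) makes per-patch classification genuinely
  imperfect — boundary and unlucky-texture patches do get mislabelled —
  without making the task hopeless. Classes sharing a lambda share one
  field, so texture is continuous across the functional/non-FLR boundary.
  Fields are renormalised by the theoretical convolution variance, exact
  away from the zero-padded grid border.
* **Metadata and outcome.** Height ~ N(170, 10) cm, weight ~ N(75, 12) kg
  (truncated to validity), modulation-to-imaging delay uniform on 7–22 days
  (ALPPS) or 36–106 days (PVE). Severe PHLF is drawn from
  `P(PHLF >= B) = plogis(2.0 - 0.08 x FRFxV%)`: 50% risk at a true
  functional remnant of 25%, ~12% at 50%, strictly decreasing. Severe cases
  split C:B as 1:2; non-severe cases are grade A with probability 0.22.
  Under the cohort defaults this yields on the order of 6 severe cases per
  24 — the clinical ballpark for modulated-hepatectomy series.

Every generator is a pure function of its parameters and an integer seed;
per-case seeds derive from the master seed by a counter scheme, so cohorts
are reproducible and cases mutually independent.

**What the phantoms do not emulate:** real vascular trees, respiratory
motion, CT reconstruction physics, scanner-dependent noise, registration
error between timepoints, or biological coupling between oedema and growth
beyond the technique-level means. Passing tests on phantoms therefore
demonstrates that the pipeline recovers known composition under its own
texture model — a necessary condition — not that the specific HU contrasts
transfer to patient CT.

## Outcome analyses

`primary_outcome()` scores FRFxV, FRLV, sFLR and KGR as predictors of severe
PHLF by ROC AUC with a *lower-is-positive* orientation (smaller remnants
mean higher risk), so AUCs land above 0.5 when a predictor works in the
expected direction. The ROC implementation sweeps unique score thresholds
with half-credit for ties, making the AUC exactly `U / (n_pos x n_neg)` —
an identity the tests assert to 1e-12. `secondary_outcome()` contrasts the
volumetric parameters between ALPPS and PVE.

Group comparisons use the Mann-Whitney U test with mid-rank ties: exact
two-sided p by enumeration of all label assignments when `n1 + n2 <= 12`,
otherwise a tie-corrected normal approximation with continuity correction
(the clinical group sizes of interest, 18 vs 6, take the approximation
path). Chi-square (Pearson, no continuity correction), Spearman correlation
and a Shapiro-Wilk normality screen wrap the standard library routines; the
Shapiro-Wilk result is reported but never gates anything. No
multiple-testing correction is applied — the tables print raw p-values with
a note, mirroring how such exploratory surgical series are reported.

## Problem sizes and runtime choices

The shipped tests and the acceptance script size their simulations for a
single CPU: classifier training uses an 8-case cohort (~20k labelled
patches); oedema-recovery checks use 20 phantoms over
theta in {0, 0.25, 0.5, 0.75}; the predictor-comparison study uses 100
replicate 24-case cohorts (the acceptance script reports medians over 30);
the growth-dissociation study uses 100 (script: 40) replicates from masks
alone, which is exact because those endpoints depend only on truth
volumetry. Intensity volumes are synthesised only for the timepoints a
given analysis reads.

## Known limitations

* The catalogue's family sizes and member lists are frozen by this package;
  other radiomics software enumerates slightly different sets, so absolute
  feature values should be compared only under matching definitions
  (bin width, aggregation, population-vs-sample variance).
* Hard patch assignment quantises FRFx in 1 cc steps and slightly
  under-resolves the functional/oedema interface; the residual bias is
  measured (not assumed) by the theta-recovery tests.
* The outcome model links PHLF to true FRFxV% only; clinical covariates
  (bilirubin, INR, age) are outside its scope.
* Mesh volume is the smoothed-surface volume and will read a few percent
  below the voxel volume for small or high-curvature masks; both are
  reported separately.
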