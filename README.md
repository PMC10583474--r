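# frfx

Functional liver remnant volumetry and texture-based oedema quantification.

## The problem

Staged hepatectomy after hepatic modulation — ALPPS or portal vein
embolisation (PVE) — relies on the future liver remnant (FLR) growing large
enough to sustain the patient. But CT volumetry measures *anatomic* growth,
and rapid regeneration (especially after ALPPS) inflates the remnant with
oedema and venous congestion that adds volume without function. The
clinically meaningful quantity is the **functional** remnant: the truly
hypertrophied parenchyma. `frfx` estimates it from CT texture.

The package is aimed at hepatobiliary imaging researchers: it implements the
full computational chain as tested, seeded, reproducible code, together with
a synthetic liver-phantom generator so every stage can be exercised and
validated without patient data.

## What it computes

**Volumetry** (volumes in cc, measured by voxel counting on segmentation
masks; TLV and TV from the pre-modulation study):

    FRLV%  = FRL  / (TLV - TV) x 100        anatomic remnant fraction
    FRFxV% = FRFx / (TLV - TV) x 100        functional remnant fraction
    iFRL%  = (FRLpost - FRLpre) / FRLpre x 100     (identically iFRFx%)
    BSA    = sqrt(height_cm x weight_kg / 3600)    (Mosteller, m^2)
    sFLR   = FRL / (-794.41 + 1267.28 x BSA) x 100
    KGR    = (FRLV%post - FRLV%pre) / days         (percentage points/day)

**Radiomics**: a frozen 106-feature catalogue per region — 19 first-order,
16 shape (marching-tetrahedra mesh), 22 GLCM, 16 GLRLM, 16 GLSZM, 12 GLDM,
5 NGTDM — with fixed 25 HU bins anchored at the region minimum and features
averaged over the 13 unique 3-D directions.

**Classification**: patches (4^3 voxels = 1 cc) of the vessel- and
tumour-free FLR parenchyma are standardised, ranked by information gain
within the first-order family, and classified functional-vs-oedema by an
L2-penalised logistic regression; the functional remnant volume FRFx is the
total volume of functional-labelled parenchyma.

**Cohort statistics**: Mann-Whitney U (exact by enumeration at
n1 + n2 <= 12), Pearson chi-square, Spearman, Shapiro-Wilk screening, and
ROC/AUC with the exact AUC = U/(n1 n2) tie convention. `primary_outcome()`
scores FRFxV, FRLV, sFLR and KGR as predictors of severe post-hepatectomy
liver failure (PHLF >= B, lower-is-positive); `secondary_outcome()`
contrasts anatomic vs functional growth between ALPPS and PVE.

**Phantoms**: paired pre/post CT-like volumes (64^3 voxels, 2.5 mm) with an
ellipsoid liver, planar FLR split, tumour, vessels, chamfer-grown remnant,
a rim-placed oedema fraction of known size, correlated Gaussian-field
textures, and PHLF outcomes drawn from a logistic link that decreases in
the true functional remnant fraction.

## Worked example

```r
library(frfx)

# a paired pre/post phantom case: ALPPS-like growth with oedema
case <- generate_case(default_sim_params("ALPPS"), seed = 42)
case
#> <phantom_case> case_00000042 (ALPPS): FRL 982 cc, FRFx 464 cc (theta 0.53), PHLF A

# train the functional-tissue classifier on a small phantom cohort
cohort <- generate_cohort(n = 8, technique_split = c(4, 4), seed = 500)
fit <- train_functional_classifier(cohort$cases)
head(fit$selection, 3)
#>   feature info_gain        t p rank candidate selected
#> 1 fo_mean 0.4904223 137.2077 0    1      TRUE     TRUE
#> 2  fo_rms 0.4890192 136.8232 0    2      TRUE     TRUE
#> 3  fo_p10 0.4810311 132.6690 0    3      TRUE     TRUE

# estimate the functional remnant of the case and complete the volumetry
est <- estimate_frfx(case, fit$model)
rec <- compute_volumetry(case, frfx_pre_cc = est[["frfx_pre_cc"]],
                         frfx_post_cc = est[["frfx_post_cc"]])
round(rec$frfxv_pct, 1); round(rec$frlv_pct, 1); round(case$true_frfxv_pct, 1)
#> [1] 32
#> [1] 69
#> [1] 32.6
```

The classifier reads a 69% anatomic remnant (FRLV) as only 32% functional
(FRFxV) — within a percentage point of the phantom's known truth (32.6%):
the case carries a 53% oedema fraction, which voxel counting alone cannot
see.

`run_pipeline(pipeline_config(seed = 1))` chains the whole study — simulate,
train on one half of the cohort, classify the held-out half, volumetry, and
the PHLF / technique outcome tables — and writes every artefact (CSV, JSON
model, Markdown report, md5 manifest) to the configured output directory.

## Scope

The package operates on aligned volumes with given segmentation masks
(NIfTI-1). DICOM ingestion, image registration, CNN/contour segmentation,
Couinaud subdivision and rendering are out of scope by design.
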