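Package: frfx
Title: Functional Liver Remnant Volumetry and Texture-Based Oedema Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for distinguishing the functional future liver remnant (true
    hypertrophy) from the anatomic future liver remnant (hypertrophy plus
    oedema/congestion) on CT-like volumes after hepatic modulation (ALPPS or
    portal vein embolisation). Implements future-liver-remnant volumetry (FRLV,
    FRFxV, iFRL, iFRFx, BSA-standardised FLR, kinetic growth rate), a
    106-feature radiomic catalogue (first-order, shape, GLCM, GLRLM, GLSZM,
    GLDM, NGTDM), an information-gain plus logistic-regression patch classifier
    that converts texture into functional-volume estimates, cohort statistics
    (Mann-Whitney, chi-square, Spearman, Shapiro-Wilk, ROC/AUC), and a seeded
    synthetic liver-phantom generator with known oedema composition and
    simulated post-hepatectomy liver failure outcomes so that every stage of
    the pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust
Config/testthat/edition: 3
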