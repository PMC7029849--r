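Package: renocomp
Title: Kidney Compartment Volumetry from Dixon MRI with Cohort
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-automated segmentation of the kidneys and their internal
    compartments (parenchyma, renal sinus, sinus fat, pelvis) from
    water-fat-separated (Dixon) magnetic resonance volumes, together with
    voxel-summation volumetry and the cohort-level statistics used to relate
    renal compartment volumes to glycemic status and visceral adiposity.
    Includes a synthetic Dixon phantom generator with ground-truth labels, a
    synthetic three-group (normoglycemic, prediabetes, diabetes) cohort
    simulator, clinical derivations (WHO oral glucose tolerance test
    classification, CKD-EPI estimated glomerular filtration rate,
    hypertension rule, urine albumin-creatinine ratio), adjusted linear
    association models, Pearson correlations with Fisher confidence
    intervals, two-way random-effects intraclass correlation, and
    Bland-Altman limits of agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
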