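# renocomp

Kidney compartment volumetry from water–fat-separated (Dixon) MRI, with
the cohort statistics that relate renal volumes to metabolic disease.

## What it is for

Renal sinus fat — the perivascular fat depot inside the renal hilum — is a
candidate imaging biomarker for early metabolic kidney involvement: it
increases with visceral adiposity and glucose intolerance before overt
renal dysfunction. Measuring it from abdominal MR requires segmenting each
kidney away from liver, spleen and bowel, subdividing the kidney into
parenchyma, sinus fat and fluid/pelvis, and converting labels to volumes
by voxel summation. `renocomp` implements that pipeline, plus the
statistical layer used to analyse such volumes across a three-group cohort
(normoglycemic control, prediabetes, diabetes), for image-analysis and
epidemiology researchers who want a tested, reproducible reference
implementation.

Because no public image accession exists for this study design, the
package also ships two synthetic generators as first-class components:

* a **Dixon phantom** (`generate_phantom()`) — two ellipsoidal kidneys
  with hilar sinus fat, fluid and pelvis inside a soft-tissue torso, with
  liver/spleen confounders and voxel-level ground-truth labels;
* a **cohort simulator** (`simulate_cohort()`) — 366 subjects in groups of
  230/87/49 with the published covariate means/SDs, outcomes generated
  from published linear coefficient sets.

## The core methods

* **Segmentation**: Otsu thresholding of the water image inside the body
  mask → prior-box connected-component selection per flank →
  region-competition active-contour refinement on the water channel
  (robust parenchyma model, morphological regularization) → compartment
  separation inside the whole-kidney mask: sinus voxels have water signal
  < 0.6 × the parenchyma reference; among them, fat fraction
  F/(W+F) > 0.5 labels sinus fat and < 0.2 labels pelvis/fluid. Output
  classes partition the kidney mask exactly.
* **Volumetry**: volume = voxel count × voxel volume, in ml.
* **Clinical derivations**: WHO OGTT glycemic classification, the
  hypertension rule (≥140/≥90 mmHg or aware medicated), CKD-EPI 2009 eGFR,
  and urine albumin–creatinine ratio.
* **Statistics**: OLS association models with t-based 95% CIs and adjusted
  R²; Pearson correlation with Fisher-transform CI; ICC(2,1)
  (single-measure absolute agreement from two-way random-effects ANOVA,
  F-based CI); Bland–Altman limits of agreement (mean difference
  ± 1.96 SD); size-weighted pooled means.

See the methods vignette
(`vignettes/renal-sinus-fat-volumetry.Rmd`) for the full model
description, parameter rationale, and what the synthetic benchmarks do and
do not establish.

## Worked example

```r
library(renocomp)

# phantom -> segmentation -> volumetry
ph  <- generate_phantom(phantom_config(seed = 1))
seg <- segment_kidneys(ph$dixon)
compute_volumes(seg$labels)
#> Compartment volumes
#>   Renal volume: 240.1 ml
#>   Sinus volume: 35.9 ml
#>   Sinus fat:    23.2 ml
ground_truth_volumes(ph$truth)   # identical on the default noiseless phantom
```

The default phantom's two kidneys total 240 ml, of which 36 ml is sinus
and 23 ml sinus fat; the segmentation recovers the ground-truth volumes
exactly at default geometry and noise 0.

```r
# cohort -> age/sex-adjusted association with glycemic status
co  <- simulate_cohort(cohort_params(seed = 1))
fit_linear_model(co, "sinus_fat_ml", c("age", "sex", "glycemic_status"))
#> Linear association model: sinus_fat_ml ~ age + sexfemale + ...
#>                        term    beta              ci        p
#>                 (Intercept)  21.200    [13.9, 28.5] 2.46e-08
#>                         age   0.143 [0.0143, 0.272]   0.0296
#>                   sexfemale -15.000  [-17.3, -12.6]  < 2e-16
#>  glycemic_statusprediabetes   8.020    [5.22, 10.8] 3.57e-08
#>     glycemic_statusdiabetes   7.960    [4.47, 11.4] 9.57e-06
#> n = 366 (0 dropped), adjusted R^2 = 0.423
```

Prediabetic subjects carry on average ~8 ml more sinus fat than controls
of the same age and sex in this simulated draw; the generating coefficient
is 7.13 ml.

```r
# inter-reader agreement under the calibrated reader-error model
d <- simulate_reader_pair(33, 68.7, 9.79, seed = 1)
icc_two_way_random(d)
#> ICC(2,1) = 0.98 [0.96, 0.99] (n = 33 subjects, k = 2 raters)
limits_of_agreement(d$reader1, d$reader2)
#> Mean difference 0.7 (0.4%), 95% limits of agreement [-24.6, 26.0], n = 33
```

A full phantom-to-statistics run with artifacts and a reproducibility
manifest:

```r
run_pipeline(pipeline_config(seed = 1, out_dir = "out"))
```

A thin shell wrapper with per-stage subcommands is installed at
`inst/scripts/renocomp`.

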