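# Clinical classifications and renal-function measures derived from raw
# covariates: WHO OGTT glycemic status, hypertension rule, CKD-EPI eGFR and
# the urine albumin-creatinine ratio.

#' Classify glycemic status from an oral glucose tolerance test
#'
#' WHO criteria on fasting and 2-hour serum glucose (mg/dl): diabetes if the
#' 2-h value exceeds 200 or fasting exceeds 125 (this rule takes
#' precedence); prediabetes if the 2-h value lies in [140, 200] (impaired
#' glucose tolerance) or fasting lies in [110, 125] (impaired fasting
#' glucose); otherwise normoglycemic control. Boundary values are read as
#' closed prediabetes intervals, consistent with the strict inequalities of
#' the diabetes rule.
#'
#' @param fasting,two_hour Serum glucose in mg/dl; vectorized.
#' @return A data frame with columns `status` (factor: control,
#'   prediabetes, diabetes, unclassifiable) and `prediabetes_type` (factor:
#'   IFG, IGT, both, or NA).
#' @examples
#' classify_glycemic_status(100, 120)  # control
#' classify_glycemic_status(115, 130)  # prediabetes (IFG)
#' @export
classify_glycemic_status <- function(fasting, two_hour) {
  n <- max(length(fasting), length(two_hour))
  fasting <- rep_len(fasting, n); two_hour <- rep_len(two_hour, n)
  bad <- !is.finite(fasting) | !is.finite(two_hour)
  if (any(c(fasting[!bad], two_hour[!bad]) <= 0))
    stop("glucose values must be positive", call. = FALSE)
  status <- rep("unclassifiable", n)
  ptype <- rep(NA_character_, n)
  diab <- !bad & (two_hour > 200 | fasting > 125)
  ifg <- !bad & !diab & fasting >= 110 & fasting <= 125
  igt <- !bad & !diab & two_hour >= 140 & two_hour <= 200
  pre <- ifg | igt
  ctrl <- !bad & !diab & !pre & fasting < 110 & two_hour < 140
  status[diab] <- "diabetes"
  status[pre] <- "prediabetes"
  status[ctrl] <- "control"
  ptype[ifg & !igt] <- "IFG"
  ptype[igt & !ifg] <- "IGT"
  ptype[ifg & igt] <- "both"
  data.frame(status = factor(status, levels = c("control", "prediabetes",
                                                "diabetes", "unclassifiable")),
             prediabetes_type = factor(ptype, levels = c("IFG", "IGT", "both")))
}

#' Hypertension classification
#'
#' True iff systolic pressure >= 140 mmHg, diastolic pressure >= 90 mmHg,
#' or the subject takes antihypertensive medication while being aware of
#' having hypertension (medication without awareness does not count).
#'
#' @param sbp,dbp Blood pressures in mmHg (> 0); vectorized.
#' @param med Logical: intake of antihypertensive medication.
#' @param aware Logical: aware of having hypertension.
#' @return Logical vector.
#' @export
classify_hypertension <- function(sbp, dbp, med, aware) {
  if (any(sbp <= 0, na.rm = TRUE) || any(dbp <= 0, na.rm = TRUE))
    stop("blood pressures must be positive", call. = FALSE)
  sbp >= 140 | dbp >= 90 | (med & aware)
}

#' CKD-EPI estimated glomerular filtration rate (2009 creatinine equation)
#'
#' eGFR = 141 x min(Scr/kappa, 1)^alpha x max(Scr/kappa, 1)^-1.209
#' x 0.993^age x 1.018 (if female), with kappa = 0.7 (female) / 0.9 (male)
#' and alpha = -0.329 (female) / -0.411 (male). The race coefficient is not
#' used.
#'
#' @param creatinine Serum creatinine in mg/dl (> 0); vectorized.
#' @param age Age in years.
#' @param sex `"male"` or `"female"` (recycled).
#' @return eGFR in ml/min/1.73 m^2.
#' @examples
#' egfr_ckd_epi(1.0, 50, "male")  # about 87.4
#' @export
egfr_ckd_epi <- function(creatinine, age, sex) {
  n <- max(length(creatinine), length(age), length(sex))
  creatinine <- rep_len(creatinine, n); age <- rep_len(age, n)
  sex <- rep_len(as.character(sex), n)
  if (any(creatinine <= 0)) stop("creatinine must be positive", call. = FALSE)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  141 * pmin(creatinine / kappa, 1)^alpha *
    pmax(creatinine / kappa, 1)^(-1.209) *
    0.993^age * ifelse(female, 1.018, 1)
}

# Inverse of the CKD-EPI equation: serum creatinine that yields a target
# eGFR for given age/sex. Used by the cohort simulator, which draws eGFR
# from the reported distribution and back-computes creatinine.
creatinine_from_egfr <- function(egfr, age, sex) {
  n <- max(length(egfr), length(age), length(sex))
  egfr <- rep_len(egfr, n); age <- rep_len(age, n)
  sex <- rep_len(as.character(sex), n)
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  base <- 141 * 0.993^age * ifelse(female, 1.018, 1)
  # at Scr = kappa both branches give eGFR = base; below kappa the alpha
  # branch applies, above it the -1.209 branch
  low <- egfr >= base
  expo <- ifelse(low, 1 / alpha, 1 / -1.209)
  kappa * (egfr / base)^expo
}

#' Urine albumin-to-creatinine ratio
#'
#' @param urine_albumin Urine albumin in mg/l (>= 0).
#' @param urine_creatinine Urine creatinine in g/l (> 0).
#' @return UACR in mg/g.
#' @export
uacr <- function(urine_albumin, urine_creatinine) {
  if (any(urine_creatinine <= 0))
    stop("urine creatinine must be positive", call. = FALSE)
  if (any(urine_albumin < 0))
    stop("urine albumin must be non-negative", call. = FALSE)
  urine_albumin / urine_creatinine
}

#' Derive clinical columns for a cohort table
#'
#' Appends glycemic status (and prediabetes subtype), hypertension, eGFR
#' (CKD-EPI), UACR and the serum-creatinine enrollment filter flag
#' (creatinine >= 1.3 mg/dl) to a subject table.
#'
#' @param table Data frame with columns `fasting_glucose`, `glucose_2h`,
#'   `sbp`, `dbp`, `antihypertensive_med`, `aware_of_hypertension`,
#'   `serum_creatinine`, `age`, `sex`, `urine_albumin`, `urine_creatinine`.
#' @return The table with derived columns appended.
#' @export
derive_clinical <- function(table) {
  gs <- classify_glycemic_status(table$fasting_glucose, table$glucose_2h)
  table$glycemic_status <- gs$status
  table$prediabetes_type <- gs$prediabetes_type
  table$hypertension <- classify_hypertension(table$sbp, table$dbp,
                                              table$antihypertensive_med,
                                              table$aware_of_hypertension)
  table$egfr <- egfr_ckd_epi(table$serum_creatinine, table$age, table$sex)
  table$uacr <- uacr(table$urine_albumin, table$urine_creatinine)
  table$creatinine_excluded <- table$serum_creatinine >= 1.3
  table
}
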