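# Synthetic three-group cohort generator. Covariates are drawn per glycemic
# group from truncated normal distributions with the reported group means
# and SDs; outcomes (renal volume, sinus volume, sinus fat) follow a
# configured linear coefficient set plus Gaussian residual, with the
# residual SD solved so the marginal outcome SD matches the reported
# whole-sample SD.

# --- truncated normal: sampling + analytic moments -------------------------

rtruncnorm_icdf <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

truncnorm_moments <- function(mean, sd, lower, upper) {
  if (sd == 0) return(c(mean = mean, var = 0))
  a <- (lower - mean) / sd; b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  m <- mean + sd * (pa - pb) / Z
  apa <- if (is.finite(a)) a * pa else 0
  bpb <- if (is.finite(b)) b * pb else 0
  v <- sd^2 * (1 + (apa - bpb) / Z - ((pa - pb) / Z)^2)
  c(mean = m, var = v)
}

# --- default parameterization ---------------------------------------------

# per-covariate group means/SDs (control, prediabetes, diabetes) with
# plausibility bounds; values follow the reference cohort of 366 adults
default_covariate_table <- function() {
  cov3 <- function(m, s, lo, hi) list(mean = m, sd = s, lower = lo, upper = hi)
  list(
    age               = cov3(c(54.4, 58.1, 61.4), c(8.9, 8.6, 8.3), 18, 100),
    weight            = cov3(c(78.2, 91.5, 89.5), c(15.5, 14.9, 17.9), 35, 200),
    height            = cov3(c(171.2, 172.3, 171.3), c(10.3, 9.2, 7.9), 140, 210),
    bmi               = cov3(c(26.6, 30.9, 30.4), c(4.3, 5.0, 5.2), 14, 60),
    waist             = cov3(c(93.5, 106.6, 107.8), c(12.8, 13.0, 14.5), 50, 180),
    sbp               = cov3(c(116.6, 125.8, 131.9), c(15.2, 15.1, 20.4), 70, 220),
    dbp               = cov3(c(73.6, 78.4, 78.1), c(9.2, 9.4, 13.1), 40, 140),
    total_cholesterol = cov3(c(216.1, 225.5, 214.9), c(36.2, 32.0, 47.3), 80, 400),
    hdl               = cov3(c(65.4, 57.6, 51.9), c(18.1, 14.5, 18.4), 15, 150),
    ldl               = cov3(c(138.5, 147.6, 136.1), c(32.2, 30.1, 42.1), 30, 300),
    triglycerides     = cov3(c(106.9, 153.6, 207.9), c(64.3, 83.4, 123.2), 30, 900),
    gfr               = cov3(c(94.9, 89.3, 89.6), c(12.5, 12.2, 14.8), 15, 150),
    urine_albumin     = cov3(c(10.2, 13.5, 119.2), c(15.8, 19.1, 345.1), 0.1, 3000),
    urine_creatinine  = cov3(c(1.6, 1.6, 1.8), c(0.8, 0.7, 0.8), 0.2, 6),
    vat_l             = cov3(c(3.5, 5.8, 6.8), c(2.3, 2.3, 2.4), 0.1, 20),
    liver_fat_pct     = cov3(c(5.6, 12.3, 16.1), c(5.1, 7.8, 9.3), 0.5, 45))
}

# coefficient sets for the two generating models, per outcome
default_outcome_models <- function() {
  list(
    age_sex_status = list(
      renal_volume_ml = c(age = -1.35, sex_female = -79.04,
                          prediabetes = 18.65, diabetes = 31.90),
      sinus_volume_ml = c(age = 0.25, sex_female = -16.58,
                          prediabetes = 10.08, diabetes = 11.86),
      sinus_fat_ml    = c(age = 0.27, sex_female = -13.95,
                          prediabetes = 7.13, diabetes = 7.34)),
    age_sex_vat = list(
      renal_volume_ml = c(age = -1.53, vat_l = 6.06, sex_female = -66.35),
      sinus_volume_ml = c(age = 0.13, vat_l = 3.57, sex_female = -8.30),
      sinus_fat_ml    = c(age = 0.15, vat_l = 2.75, sex_female = -7.43)))
}

#' Cohort simulation parameters
#'
#' Defaults reproduce the structure of a population-based three-group study
#' sample of 366 adults: group sizes 230 (normoglycemic control), 87
#' (prediabetes) and 49 (diabetes); per-group covariate means and SDs;
#' and per-outcome linear coefficient sets for the generating model of the
#' renal volumes. The residual SD of each outcome is solved analytically
#' (law of total variance over the truncated-normal covariates and the
#' group mixture) so the marginal outcome SD matches `target_sd`.
#'
#' @param group_sizes Named integer vector (control, prediabetes, diabetes).
#' @param outcome_model `"age_sex_status"` (glycemic-status model) or
#'   `"age_sex_vat"` (visceral-fat model): which coefficient set generates
#'   the outcomes.
#' @param covariates Per-covariate list of group means/SDs and bounds; see
#'   `default_covariate_table()` source for the expected shape.
#' @param coefficients Per-outcome named coefficient vectors for the chosen
#'   model.
#' @param target_mean,target_sd Whole-sample outcome means/SDs (renal,
#'   sinus, sinus fat) used to place the intercept and size the residual.
#' @param male_prop Per-group probability of male sex.
#' @param med_prop Per-group probability of antihypertensive medication.
#' @param aware_given_med Probability of hypertension awareness given
#'   medication.
#' @param residual_sd Optional named numeric vector overriding the solved
#'   residual SD per outcome (e.g. `c(sinus_fat_ml = 0)` for a noiseless
#'   generating model).
#' @param derive_status_from_glucose Logical: when TRUE the glycemic status
#'   column is re-derived from the simulated OGTT values via
#'   [classify_glycemic_status()] instead of being copied from the design
#'   group (the simulated glucose is drawn within class-consistent ranges,
#'   so the two coincide; the flag exercises the clinical module
#'   end-to-end).
#' @param seed Integer seed.
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(group_sizes = c(control = 230L, prediabetes = 87L,
                                          diabetes = 49L),
                          outcome_model = c("age_sex_status", "age_sex_vat"),
                          covariates = default_covariate_table(),
                          coefficients = NULL,
                          target_mean = c(renal_volume_ml = 291.3,
                                          sinus_volume_ml = 40.0,
                                          sinus_fat_ml = 26.2),
                          target_sd = c(renal_volume_ml = 68.7,
                                        sinus_volume_ml = 18.0,
                                        sinus_fat_ml = 13.6),
                          male_prop = c(0.509, 0.632, 0.735),
                          med_prop = c(0.165, 0.333, 0.490),
                          aware_given_med = 0.9,
                          residual_sd = NULL,
                          derive_status_from_glucose = FALSE,
                          seed = 1L) {
  outcome_model <- match.arg(outcome_model)
  if (any(group_sizes < 0)) stop("group sizes must be >= 0", call. = FALSE)
  if (is.null(coefficients))
    coefficients <- default_outcome_models()[[outcome_model]]
  for (cv in covariates)
    if (any(cv$sd < 0)) stop("covariate SDs must be >= 0", call. = FALSE)
  if (!is.null(residual_sd) && any(residual_sd < 0))
    stop("residual SDs must be >= 0", call. = FALSE)
  structure(list(group_sizes = group_sizes,
                 outcome_model = outcome_model,
                 covariates = covariates,
                 coefficients = coefficients,
                 target_mean = target_mean,
                 target_sd = target_sd,
                 male_prop = male_prop,
                 med_prop = med_prop,
                 aware_given_med = aware_given_med,
                 residual_sd = residual_sd,
                 derive_status_from_glucose = derive_status_from_glucose,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

# Analytic mean/variance of the linear predictor for one outcome under the
# mixture of groups, and the implied intercept and residual SD.
linpred_calibration <- function(params, outcome) {
  beta <- params$coefficients[[outcome]]
  w <- params$group_sizes / sum(params$group_sizes)
  gm <- gv <- numeric(3)
  for (g in 1:3) {
    m <- 0; v <- 0
    for (term in names(beta)) {
      b <- beta[[term]]
      if (term == "sex_female") {
        p <- 1 - params$male_prop[g]
        m <- m + b * p; v <- v + b^2 * p * (1 - p)
      } else if (term == "prediabetes") {
        m <- m + b * (g == 2L)
      } else if (term == "diabetes") {
        m <- m + b * (g == 3L)
      } else {
        cv <- params$covariates[[term]]
        if (is.null(cv)) stop("unknown model term: ", term, call. = FALSE)
        mom <- truncnorm_moments(cv$mean[g], cv$sd[g], cv$lower, cv$upper)
        m <- m + b * mom[["mean"]]; v <- v + b^2 * mom[["var"]]
      }
    }
    gm[g] <- m; gv[g] <- v
  }
  mean_lp <- sum(w * gm)
  var_lp <- sum(w * gv) + sum(w * (gm - mean_lp)^2)
  target_var <- params$target_sd[[outcome]]^2
  res_var <- target_var - var_lp
  if (res_var < 0) {
    warning("linear predictor variance exceeds the target marginal SD for ",
            outcome, "; residual SD floored at 0", call. = FALSE)
    res_var <- 0
  }
  list(intercept = params$target_mean[[outcome]] - mean_lp,
       residual_sd = sqrt(res_var))
}

# group-conditional OGTT values drawn inside the class-defining ranges, so
# classification round-trips (distributions themselves are synthetic: the
# reference table reports no glucose values)
simulate_ogtt <- function(group) {
  n <- length(group)
  fasting <- numeric(n); two_h <- numeric(n)
  for (g in levels(group)) {
    i <- which(group == g)
    if (!length(i)) next
    if (g == "control") {
      fasting[i] <- rtruncnorm_icdf(length(i), 95, 8, 70, 109.5)
      two_h[i] <- rtruncnorm_icdf(length(i), 110, 15, 70, 139.5)
    } else if (g == "prediabetes") {
      igt <- stats::runif(length(i)) < 0.5
      fasting[i] <- ifelse(igt,
                           rtruncnorm_icdf(length(i), 98, 6, 70, 109.5),
                           rtruncnorm_icdf(length(i), 117, 4, 110, 125))
      two_h[i] <- ifelse(igt,
                         rtruncnorm_icdf(length(i), 165, 15, 140, 200),
                         rtruncnorm_icdf(length(i), 120, 12, 70, 139.5))
    } else {
      fasting[i] <- rtruncnorm_icdf(length(i), 150, 25, 90, 250)
      two_h[i] <- rtruncnorm_icdf(length(i), 230, 25, 201, 400)
    }
  }
  data.frame(fasting_glucose = fasting, glucose_2h = two_h)
}

#' Simulate a synthetic cohort
#'
#' Draws per-group covariates from truncated normal distributions, derives
#' serum creatinine by inverting the CKD-EPI equation on the drawn eGFR, and
#' generates the three volume outcomes from the configured linear model plus
#' Gaussian residual. Deterministic for a fixed `params$seed`.
#'
#' @param params A [cohort_params()].
#' @return A data frame, one row per subject, with design group
#'   (`glycemic_status`), demographics, clinical covariates, OGTT values and
#'   the outcome columns `renal_volume_ml`, `sinus_volume_ml`,
#'   `sinus_fat_ml`.
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  ns <- params$group_sizes
  n <- sum(ns)
  group <- factor(rep(c("control", "prediabetes", "diabetes"), times = ns),
                  levels = c("control", "prediabetes", "diabetes"))
  gi <- as.integer(group)
  sex <- factor(ifelse(stats::runif(n) < params$male_prop[gi],
                       "male", "female"),
                levels = c("male", "female"))
  tab <- data.frame(id = sprintf("S%04d", seq_len(n)),
                    glycemic_status = group, sex = sex,
                    stringsAsFactors = FALSE)
  for (nm in names(params$covariates)) {
    cv <- params$covariates[[nm]]
    x <- numeric(n)
    for (g in 1:3) {
      i <- which(gi == g)
      x[i] <- rtruncnorm_icdf(length(i), cv$mean[g], cv$sd[g],
                              cv$lower, cv$upper)
    }
    tab[[nm]] <- x
  }
  tab$serum_creatinine <- creatinine_from_egfr(tab$gfr, tab$age, tab$sex)
  tab$uacr <- uacr(tab$urine_albumin, tab$urine_creatinine)
  tab$antihypertensive_med <- stats::runif(n) < params$med_prop[gi]
  tab$aware_of_hypertension <- tab$antihypertensive_med &
    stats::runif(n) < params$aware_given_med
  tab$hypertension <- classify_hypertension(tab$sbp, tab$dbp,
                                            tab$antihypertensive_med,
                                            tab$aware_of_hypertension)
  ogtt <- simulate_ogtt(group)
  tab$fasting_glucose <- ogtt$fasting_glucose
  tab$glucose_2h <- ogtt$glucose_2h
  if (params$derive_status_from_glucose)
    tab$glycemic_status <- classify_glycemic_status(tab$fasting_glucose,
                                                    tab$glucose_2h)$status

  female <- tab$sex == "female"
  for (outcome in names(params$coefficients)) {
    beta <- params$coefficients[[outcome]]
    cal <- linpred_calibration(params, outcome)
    if (!is.null(params$residual_sd) && outcome %in% names(params$residual_sd))
      cal$residual_sd <- params$residual_sd[[outcome]]
    lp <- rep(cal$intercept, n)
    for (term in names(beta)) {
      b <- beta[[term]]
      lp <- lp + b * switch(term,
        sex_female = as.numeric(female),
        prediabetes = as.numeric(gi == 2L),
        diabetes = as.numeric(gi == 3L),
        tab[[term]])
    }
    tab[[outcome]] <- lp + stats::rnorm(n, 0, cal$residual_sd)
  }
  attr(tab, "params") <- params
  tab
}

#' Simulate a paired-reader measurement set
#'
#' True volumes are drawn from Normal(`mean`, `between_sd`); each of two
#' readers observes the truth plus independent Normal(0, `reader_sd`) error.
#' Used to study inter-reader agreement (ICC, limits of agreement) under a
#' known error model.
#'
#' @param n Number of subjects (>= 3).
#' @param between_sd Between-subject SD of the true volumes (ml).
#' @param reader_sd Per-reader measurement error SD (ml).
#' @param mean Mean true volume (ml).
#' @param seed Optional integer seed.
#' @return Data frame with columns `reader1`, `reader2` (and attribute
#'   `truth`).
#' @export
simulate_reader_pair <- function(n, between_sd, reader_sd, mean = 291.3,
                                 seed = NULL) {
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  if (between_sd < 0 || reader_sd < 0) stop("SDs must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  truth <- stats::rnorm(n, mean, between_sd)
  out <- data.frame(reader1 = truth + stats::rnorm(n, 0, reader_sd),
                    reader2 = truth + stats::rnorm(n, 0, reader_sd))
  attr(out, "truth") <- truth
  out
}
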