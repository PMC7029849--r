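# Inference layer: adjusted OLS association models, Pearson correlation
# with Fisher confidence intervals, two-way random-effects ICC, Bland-Altman
# limits of agreement, and weighted group summaries.

#' Fit an adjusted linear association model
#'
#' Ordinary least squares of one outcome on a set of terms, complete cases
#' only, with 95% confidence intervals from the t distribution and the
#' adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1). Categorical terms are
#' expanded to indicator contrasts against their first level (the package
#' conventions put the reference at control / male / no hypertension).
#'
#' @param table Data frame.
#' @param outcome Name of the outcome column.
#' @param terms Character vector of predictor columns.
#' @param conf_level Confidence level for the intervals.
#' @return Object of class `renal_lm` with elements `outcome`, `terms`
#'   (data frame: term, beta, ci_low, ci_high, p), `adj_r_squared`,
#'   `n_used`, `n_dropped` and the underlying `lm` fit.
#' @export
fit_linear_model <- function(table, outcome, terms, conf_level = 0.95) {
  stopifnot(is.data.frame(table), outcome %in% names(table),
            all(terms %in% names(table)))
  cols <- c(outcome, terms)
  cc <- stats::complete.cases(table[cols])
  dat <- table[cc, cols, drop = FALSE]
  n <- nrow(dat)
  if (n <= length(terms) + 1L)
    stop("too few complete cases (", n, ") for ", length(terms), " terms",
         call. = FALSE)
  for (tm in terms) {
    v <- dat[[tm]]
    if ((is.factor(v) || is.character(v) || is.logical(v)) &&
        length(unique(v)) < 2L)
      stop("rank-deficient design; no variation in term: ", tm, call. = FALSE)
  }
  fml <- stats::reformulate(terms, response = outcome)
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < length(stats::coef(fit))) {
    aliased <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  res <- data.frame(term = rownames(sm$coefficients),
                    beta = sm$coefficients[, 1],
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    p = sm$coefficients[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(outcome = outcome, terms = res,
                 adj_r_squared = sm$adj.r.squared,
                 r_squared = sm$r.squared,
                 n_used = n, n_dropped = sum(!cc),
                 conf_level = conf_level, fit = fit),
            class = "renal_lm")
}

#' @export
print.renal_lm <- function(x, digits = 3, ...) {
  cat("Linear association model: ", x$outcome, " ~ ",
      paste(setdiff(x$terms$term, "(Intercept)"), collapse = " + "),
      "\n", sep = "")
  tt <- x$terms
  tt$beta <- signif(tt$beta, digits)
  tt$ci <- sprintf("[%s, %s]", signif(tt$ci_low, digits),
                   signif(tt$ci_high, digits))
  tt$p <- format.pval(tt$p, digits = digits)
  print(tt[c("term", "beta", "ci", "p")], row.names = FALSE)
  cat(sprintf("n = %d (%d dropped), adjusted R^2 = %.3f\n",
              x$n_used, x$n_dropped, x$adj_r_squared))
  invisible(x)
}

#' @export
coef.renal_lm <- function(object, ...) {
  stats::setNames(object$terms$beta, object$terms$term)
}

#' @export
confint.renal_lm <- function(object, ...) {
  m <- as.matrix(object$terms[c("ci_low", "ci_high")])
  rownames(m) <- object$terms$term
  m
}

#' @export
summary.renal_lm <- function(object, ...) summary(object$fit, ...)

#' Pearson correlation with Fisher-transform confidence interval
#'
#' Sample Pearson r with a confidence interval obtained on the Fisher z
#' scale, z +/- z_crit / sqrt(n - 3), back-transformed.
#'
#' @param x,y Numeric vectors of equal length, n >= 4, neither constant.
#' @param confidence Confidence level (default 0.95).
#' @param stratum Optional label carried into the result.
#' @return Object of class `renal_cor`: list with `r`, `ci`, `n`, `stratum`.
#' @export
pearson_with_ci <- function(x, y, confidence = 0.95, stratum = NA_character_) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    ci <- c(r, r)
  } else {
    z <- atanh(r)
    hw <- stats::qnorm(1 - (1 - confidence) / 2) / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  }
  structure(list(r = r, ci = ci, n = n, confidence = confidence,
                 stratum = stratum),
            class = "renal_cor")
}

#' @export
print.renal_cor <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson r = %.*f [%.*f, %.*f] (n = %d%s)\n", digits, x$r,
              digits, x$ci[1], digits, x$ci[2], x$n,
              if (!is.na(x$stratum)) paste0(", ", x$stratum) else ""))
  invisible(x)
}

#' Two-way random-effects intraclass correlation, single measure,
#' absolute agreement
#'
#' ICC(2,1) from the two-way random-effects ANOVA decomposition of an
#' n x k table (subjects x raters):
#' (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E)/n),
#' where MS_R, MS_C and MS_E are the row (subject), column (rater) and
#' residual mean squares. The confidence interval uses the F-distribution
#' method of McGraw and Wong with Satterthwaite degrees of freedom.
#'
#' @param measurements Numeric matrix or data frame, n >= 3 rows (subjects),
#'   k >= 2 columns (raters), no missing cells.
#' @param conf_level Confidence level.
#' @return Object of class `renal_icc`: list with `icc`, `ci`, `n`, `k` and
#'   the mean squares.
#' @export
icc_two_way_random <- function(measurements, conf_level = 0.95) {
  m <- as.matrix(measurements)
  if (any(is.na(m))) stop("missing cells are not supported", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) stop("need >= 3 subjects and >= 2 raters", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  if (mse <= 0) {
    ci <- c(icc, icc)
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }
  structure(list(icc = icc, ci = ci, n = n, k = k,
                 ms = c(rows = msr, cols = msc, error = mse),
                 conf_level = conf_level),
            class = "renal_icc")
}

#' @export
print.renal_icc <- function(x, digits = 2, ...) {
  cat(sprintf("ICC(2,1) = %.*f [%.*f, %.*f] (n = %d subjects, k = %d raters)\n",
              digits, x$icc, digits, x$ci[1], digits, x$ci[2], x$n, x$k))
  invisible(x)
}

#' Bland-Altman limits of agreement
#'
#' For paired measurements `a`, `b`: mean difference d = mean(a - b), 95%
#' limits of agreement d +/- 1.96 sd(a - b), and the relative mean
#' difference in percent. The relative difference uses the mean of the
#' per-pair ratios d_i / ((a_i + b_i)/2) by default (`"pairwise"`); the
#' alternative `"grand"` divides the mean difference by the grand mean of
#' the pair averages.
#'
#' @param a,b Numeric vectors of equal length, n >= 2.
#' @param relative `"pairwise"` or `"grand"` denominator convention.
#' @return Object of class `renal_loa`: list with `mean_diff`,
#'   `relative_pct`, `loa` (lower, upper), `sd_diff`, `n`.
#' @export
limits_of_agreement <- function(a, b, relative = c("pairwise", "grand")) {
  relative <- match.arg(relative)
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  loa <- md + c(-1.96, 1.96) * sdd
  pm <- (a + b) / 2
  rel <- if (relative == "pairwise") mean(d / pm) * 100 else md / mean(pm) * 100
  structure(list(mean_diff = md, relative_pct = rel,
                 loa = c(lower = loa[1], upper = loa[2]),
                 sd_diff = sdd, n = length(a), relative_method = relative),
            class = "renal_loa")
}

#' @export
print.renal_loa <- function(x, digits = 1, ...) {
  cat(sprintf("Mean difference %.*f (%.*f%%), 95%% limits of agreement [%.*f, %.*f], n = %d\n",
              digits, x$mean_diff, digits, x$relative_pct,
              digits, x$loa[1], digits, x$loa[2], x$n))
  invisible(x)
}

#' Sample-size-weighted pooled mean
#'
#' Combines per-group means into the whole-sample mean:
#' sum(n_i m_i) / sum(n_i).
#'
#' @param group_means,group_ns Equal-length numeric vectors, all `group_ns`
#'   positive.
#' @return The pooled mean.
#' @examples
#' pooled_mean(c(280.3, 303.7, 320.6), c(230, 87, 49))  # 291.3
#' @export
pooled_mean <- function(group_means, group_ns) {
  if (!length(group_means) || length(group_means) != length(group_ns))
    stop("group_means and group_ns must be nonempty and of equal length",
         call. = FALSE)
  if (any(group_ns <= 0)) stop("group sizes must be positive", call. = FALSE)
  sum(group_ns * group_means) / sum(group_ns)
}

#' Run the study's association model battery
#'
#' Fits the three model specifications for each of the three volume
#' outcomes (renal volume, sinus volume, sinus fat):
#' \describe{
#'   \item{m1}{age + sex + glycemic status}
#'   \item{m2}{m1 + VAT + HDL + LDL + UACR + liver fat + GFR + hypertension,
#'     fitted on the raw covariate scale and, in addition, with standardized
#'     (unit-SD) continuous covariates}
#'   \item{m3}{age + sex + VAT}
#' }
#'
#' @param table Cohort data frame (e.g. from [simulate_cohort()]) with the
#'   required columns.
#' @param models Subset of `c("m1", "m2", "m3")`.
#' @return List with `fits` (named list of `renal_lm`, names
#'   `<model>.<outcome>`; m2 additionally as `m2z.<outcome>` on the
#'   standardized scale) and `tidy` (long-format data frame: model, outcome,
#'   term, beta, ci_low, ci_high, p, adj_r_squared, n).
#' @export
run_association_models <- function(table, models = c("m1", "m2", "m3")) {
  models <- match.arg(models, several.ok = TRUE)
  outcomes <- c("renal_volume_ml", "sinus_volume_ml", "sinus_fat_ml")
  specs <- list(
    m1 = c("age", "sex", "glycemic_status"),
    m2 = c("age", "sex", "glycemic_status", "vat_l", "hdl", "ldl", "uacr",
           "liver_fat_pct", "gfr", "hypertension"),
    m3 = c("age", "sex", "vat_l"))
  cont_m2 <- c("age", "vat_l", "hdl", "ldl", "uacr", "liver_fat_pct", "gfr")
  fits <- list()
  for (mid in models) {
    terms <- specs[[mid]]
    missing_cols <- setdiff(c(terms, outcomes), names(table))
    if (length(missing_cols))
      stop("cohort table lacks columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    for (oc in outcomes)
      fits[[paste(mid, oc, sep = ".")]] <- fit_linear_model(table, oc, terms)
    if (mid == "m2") {
      ztab <- table
      for (cl in cont_m2) ztab[[cl]] <- as.numeric(scale(ztab[[cl]]))
      for (oc in outcomes)
        fits[[paste("m2z", oc, sep = ".")]] <- fit_linear_model(ztab, oc, terms)
    }
  }
  tidy <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cbind(data.frame(model = parts[1], outcome = parts[2],
                     stringsAsFactors = FALSE),
          f$terms,
          adj_r_squared = f$adj_r_squared, n = f$n_used)
  }))
  rownames(tidy) <- NULL
  list(fits = fits, tidy = tidy)
}
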