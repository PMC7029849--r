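# Independent normal-equations OLS oracle: beta = (X'X)^-1 X'y with
# t-based confidence intervals. Used to verify fit_linear_model.
ols_oracle <- function(y, X, conf = 0.95) {
  Xd <- cbind(1, X)
  XtX <- t(Xd) %*% Xd
  beta <- solve(XtX, t(Xd) %*% y)
  res <- y - Xd %*% beta
  n <- length(y); p <- ncol(Xd)
  s2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(solve(XtX)) * s2)
  tq <- qt(1 - (1 - conf) / 2, n - p)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(beta = drop(beta), se = se,
       ci = cbind(drop(beta) - tq * se, drop(beta) + tq * se),
       p = 2 * pt(-abs(drop(beta) / se), n - p),
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p))
}

test_that("OLS fits agree with the normal-equations oracle on small datasets", {
  set.seed(19)
  for (rep in 1:12) {
    n <- sample(8:50, 1)
    k <- sample(1:4, 1)
    X <- matrix(rnorm(n * k), n, k)
    y <- drop(1.5 + X %*% runif(k, -2, 2) + rnorm(n))
    dat <- as.data.frame(X)
    names(dat) <- paste0("x", seq_len(k))
    dat$y <- y
    f <- fit_linear_model(dat, "y", paste0("x", seq_len(k)))
    orc <- ols_oracle(y, X)
    expect_equal(f$terms$beta, unname(orc$beta), tolerance = 1e-9)
    expect_equal(f$terms$ci_low, unname(orc$ci[, 1]), tolerance = 1e-9)
    expect_equal(f$terms$ci_high, unname(orc$ci[, 2]), tolerance = 1e-9)
    expect_equal(f$terms$p, unname(orc$p), tolerance = 1e-9)
    expect_equal(f$adj_r_squared, orc$adj_r2, tolerance = 1e-9)
  }
})

test_that("a five-point textbook dataset reproduces hand-computed estimates", {
  dat <- data.frame(x = 1:5, y = c(2, 4, 5, 4, 5))
  f <- fit_linear_model(dat, "y", "x")
  orc <- ols_oracle(dat$y, matrix(dat$x))
  expect_equal(coef(f)[["x"]], orc$beta[2], tolerance = 1e-12)
  expect_equal(unname(confint(f)["x", ]), unname(orc$ci[2, ]), tolerance = 1e-12)
})

test_that("an exact linear relation fits with zero-width intervals", {
  dat <- data.frame(x = seq(0, 4, by = 0.5))
  dat$y <- 3 + 2 * dat$x
  f <- suppressWarnings(fit_linear_model(dat, "y", "x"))
  expect_equal(coef(f)[["x"]], 2, tolerance = 1e-12)
  expect_equal(f$terms$ci_high - f$terms$ci_low, c(0, 0), tolerance = 1e-10)
  expect_equal(f$adj_r_squared, 1, tolerance = 1e-12)
})

test_that("collinear designs are rejected with the offending term named", {
  dat <- data.frame(y = rnorm(20), x1 = rnorm(20))
  dat$x2 <- 2 * dat$x1
  expect_error(fit_linear_model(dat, "y", c("x1", "x2")), "x2")
  expect_error(fit_linear_model(dat[1:2, ], "y", "x1"), "too few")
})

test_that("complete-case handling drops and reports rows with missing terms", {
  dat <- data.frame(y = rnorm(30), x = rnorm(30))
  dat$x[c(3, 9)] <- NA
  f <- fit_linear_model(dat, "y", "x")
  expect_identical(f$n_used, 28L)
  expect_identical(f$n_dropped, 2L)
})

test_that("Pearson correlation intervals follow the Fisher transform", {
  x <- 1:20
  r1 <- pearson_with_ci(x, 2 * x + 1)
  expect_equal(r1$r, 1)
  expect_equal(unname(r1$ci), c(1, 1))
  # orthogonalized pair: r = 0 and a CI symmetric about 0
  y <- rnorm(50)
  set.seed(33)
  x2 <- rnorm(50)
  y0 <- residuals(lm(y ~ x2))
  r0 <- pearson_with_ci(x2, y0)
  expect_lt(abs(r0$r), 1e-10)
  expect_equal(r0$ci[1], -r0$ci[2], tolerance = 1e-8)
  # dual route: interval agrees with cor.test's Fisher interval
  set.seed(34)
  a <- rnorm(60); b <- 0.5 * a + rnorm(60)
  got <- pearson_with_ci(a, b)
  ref <- cor.test(a, b)
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(unname(got$ci), as.vector(ref$conf.int), tolerance = 1e-9)
  expect_error(pearson_with_ci(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_with_ci(1:3, 1:3), "at least 4")
})

test_that("correlation recovery matches the generating rho at cohort scale", {
  set.seed(21)
  rho <- 0.73
  rs <- replicate(200, {
    z <- rnorm(230); e <- rnorm(230)
    pearson_with_ci(z, rho * z + sqrt(1 - rho^2) * e)$r
  })
  expect_lt(abs(mean(rs) - rho), 0.02)
})

test_that("ICC(2,1) equals the brute-force ANOVA decomposition on a toy table", {
  m <- cbind(r1 = c(9, 6, 8, 7, 10, 6), r2 = c(2, 1, 4, 1, 5, 2))
  # explicit sums of squares
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                outer(rep(1, n), colMeans(m)) + grand)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  got <- icc_two_way_random(m)
  expect_equal(got$icc, icc_oracle, tolerance = 1e-12)
  # cross-check the mean squares against aov's two-way decomposition
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(aov(y ~ subj + rater, data = df))[[1]]
  expect_equal(unname(got$ms["rows"]), tab["subj", "Mean Sq"], tolerance = 1e-9)
  expect_equal(unname(got$ms["cols"]), tab["rater", "Mean Sq"], tolerance = 1e-9)
  expect_equal(unname(got$ms["error"]), tab["Residuals", "Mean Sq"],
               tolerance = 1e-9)
})

test_that("ICC(2,1) penalizes systematic rater offsets and is bounded", {
  x <- c(3, 7, 5, 9, 4, 6, 8)
  expect_equal(icc_two_way_random(cbind(x, x))$icc, 1)
  off <- icc_two_way_random(cbind(x, x + 2))
  expect_lt(off$icc, 1)
  expect_gte(off$icc, -1)
  expect_true(off$ci[1] <= off$icc && off$icc <= off$ci[2])
  expect_error(icc_two_way_random(cbind(c(1, NA, 3), c(2, 2, 2))), "missing")
  expect_error(icc_two_way_random(cbind(1:2, 2:3)), ">= 3 subjects")
})

test_that("ICC converges to the variance-ratio limit in a large simulation", {
  set.seed(12)
  n <- 10000
  sb <- 2; se <- 1
  truth <- rnorm(n, 0, sb)
  m <- cbind(truth + rnorm(n, 0, se), truth + rnorm(n, 0, se))
  expect_equal(icc_two_way_random(m)$icc, sb^2 / (sb^2 + se^2),
               tolerance = 0.01)
})

test_that("limits of agreement match the direct formula", {
  a <- c(10, 20, 30, 40); b <- c(12, 19, 33, 40)
  got <- limits_of_agreement(a, b)
  d <- a - b
  expect_equal(got$mean_diff, mean(d))
  expect_equal(unname(got$loa),
               c(mean(d) - 1.96 * sd(d), mean(d) + 1.96 * sd(d)))
  expect_equal(got$relative_pct, mean(d / ((a + b) / 2)) * 100)
  grand <- limits_of_agreement(a, b, relative = "grand")
  expect_equal(grand$relative_pct, mean(d) / mean((a + b) / 2) * 100)
  same <- limits_of_agreement(a, a)
  expect_equal(c(same$mean_diff, unname(same$loa)), c(0, 0, 0))
  shifted <- limits_of_agreement(a, a + 2)
  expect_equal(c(shifted$mean_diff, unname(shifted$loa)), c(-2, -2, -2))
  expect_error(limits_of_agreement(1:3, 1:4), "length")
})

test_that("pooled means are size-weighted and bounded by the group means", {
  expect_equal(pooled_mean(c(5, 5, 5), c(10, 20, 30)), 5)
  set.seed(55)
  for (i in 1:10) {
    m <- rnorm(3, 100, 20); n <- sample(10:300, 3)
    pm <- pooled_mean(m, n)
    expect_gte(pm, min(m)); expect_lte(pm, max(m))
    expect_equal(pm, sum(m * n) / sum(n))
  }
  expect_error(pooled_mean(numeric(0), numeric(0)), "nonempty")
  expect_error(pooled_mean(c(1, 2), c(3, 0)), "positive")
})

test_that("the association model battery fits the three specifications", {
  co <- simulate_cohort(cohort_params(seed = 9L))
  res <- run_association_models(co)
  expect_setequal(unique(res$tidy$model), c("m1", "m2", "m2z", "m3"))
  m1 <- res$fits[["m1.sinus_fat_ml"]]
  # intercept + age + sex + two status indicators
  expect_identical(nrow(m1$terms), 5L)
  m3 <- res$fits[["m3.renal_volume_ml"]]
  expect_identical(nrow(m3$terms), 4L)
  # intercept + age + sex + 2 status + vat + hdl + ldl + uacr + liver fat +
  # gfr + hypertension
  m2 <- res$fits[["m2.sinus_volume_ml"]]
  expect_identical(nrow(m2$terms), 12L)
  # standardized m2 leaves indicator terms alone but rescales continuous betas
  m2z <- res$fits[["m2z.sinus_volume_ml"]]
  expect_equal(coef(m2z)[["vat_l"]], coef(m2)[["vat_l"]] * sd(co$vat_l),
               tolerance = 1e-8)
  # a cohort with no glycemic-status variation is a degenerate design
  allc <- co[co$glycemic_status == "control", ]
  expect_error(run_association_models(allc, "m1"), "glycemic_status")
  expect_error(run_association_models(co[, 1:4], "m3"), "lacks columns")
})
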