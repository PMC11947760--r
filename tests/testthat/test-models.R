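test_that("design matrices have the specified columns and coding", {
  cohort <- toy_cohort()
  dd <- build_design(cohort, model_spec("log_total", "B", "A"))
  expect_identical(colnames(dd$X),
                   c("(Intercept)", "groupB", "age", "sexmale", "education",
                     "diagnosisMCI", "diagnosisAD"))
  expect_equal(ncol(dd$X), 7)
  dd_v <- build_design(cohort, model_spec("log_total", "B", "A",
                                          covariates = "vascular"))
  expect_equal(ncol(dd_v$X), 10)
  expect_true(all(c("diabetes", "hypertension", "bmi") %in% colnames(dd_v$X)))

  long <- dplyr::bind_rows(cohort, dplyr::mutate(cohort, time_from_baseline_days = 400))
  dd_i <- build_design(long, model_spec("log_total", "B", "A",
                                        longitudinal = TRUE, interaction = TRUE))
  expect_equal(ncol(dd_i$X), 9)
  expect_true(all(c("time_years", "groupB:time_years") %in% colnames(dd_i$X)))
  expect_equal(max(dd_i$X[, "time_years"]), 400 / 365.25)
  # group indicator is reference-coded
  expect_setequal(unique(dd$X[, "groupB"]), c(0, 1))
})

test_that("zero volumes map to a zero log outcome", {
  cohort <- toy_cohort()
  cohort$wmh_occipital_mm3[1] <- 0
  dd <- build_design(cohort, model_spec("log_occipital", "B", "A"))
  expect_equal(dd$y[1], 0)
})

test_that("rows with missing model variables are dropped and counted", {
  cohort <- toy_cohort()
  cohort$education[2] <- NA
  cohort$bmi[3] <- NA
  dd <- build_design(cohort, model_spec("log_total", "B", "A"))
  expect_equal(dd$n_dropped, 1) # bmi not in the base covariate set
  dd_v <- build_design(cohort, model_spec("log_total", "B", "A",
                                          covariates = "vascular"))
  expect_equal(dd_v$n_dropped, 2)
  cohort$age <- 70
  expect_error(build_design(cohort, model_spec("log_total", "B", "A")),
               "constant", class = "wmhboot_design_error")
})

test_that("OLS agrees with an independent pseudo-inverse oracle", {
  set.seed(11)
  worst <- 0
  for (i in 1:100) {
    n <- sample(10:50, 1)
    p <- sample(2:8, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
    y <- rnorm(n)
    fit <- fit_ols(y, X)
    worst <- max(worst, max(abs(fit$coefficients$estimate - pinv_ols(y, X))))
  }
  expect_lt(worst, 1e-8)
})

test_that("OLS standard errors and t statistics match lm on a hand dataset", {
  X <- cbind("(Intercept)" = 1, x = c(1, 2, 3, 4, 5, 6))
  y <- c(1.1, 1.9, 3.3, 3.9, 5.2, 5.8)
  fit <- fit_ols(y, X)
  ref <- summary(lm(y ~ x, data = data.frame(x = X[, 2], y = y)))$coefficients
  expect_equal(fit$coefficients$estimate, unname(ref[, 1]), tolerance = 1e-10)
  expect_equal(fit$coefficients$std_error, unname(ref[, 2]), tolerance = 1e-10)
  expect_equal(fit$coefficients$t_statistic, unname(ref[, 3]), tolerance = 1e-10)
  expect_equal(fit$coefficients$p_value, unname(ref[, 4]), tolerance = 1e-10)
  expect_equal(fit$df, 4)
})

test_that("an exact linear response is flagged instead of reported as inference", {
  X <- cbind("(Intercept)" = 1, x = 1:6)
  y <- 2 + 3 * (1:6)
  fit <- fit_ols(y, X)
  expect_true(fit$exact_fit)
  expect_equal(fit$coefficients$estimate, c(2, 3), tolerance = 1e-9)
})

test_that("rank-deficient designs name the collinear columns", {
  X <- cbind("(Intercept)" = 1, a = 1:10, b = 2 * (1:10))
  expect_error(fit_ols(rnorm(10), X), "b", class = "wmhboot_fit_error")
})

test_that("t-statistics equal estimate over SE in all fit types", {
  cohort <- small_cohort(seed = 16, n_ref = 150, n_tgt = 60)
  f1 <- fit_wmh_model(cohort, model_spec("log_total", "Tgt", "Ref"))
  expect_equal(f1$coefficients$t_statistic,
               f1$coefficients$estimate / f1$coefficients$std_error,
               tolerance = 1e-10)
  long <- cohort_generate(small_config(seed = 16, n_ref = 150, n_tgt = 60))
  f2 <- fit_wmh_model(long, model_spec("log_total", "Tgt", "Ref",
                                       longitudinal = TRUE))
  expect_equal(f2$coefficients$t_statistic,
               f2$coefficients$estimate / f2$coefficients$std_error,
               tolerance = 1e-10)
  expect_gte(f2$var_subject, 0)
  expect_gt(f2$var_resid, 0)
})

test_that("REML reduces to OLS when the subject variance is zero", {
  # deterministic boundary case: equal subject means put all variation
  # within subjects, so the REML optimum sits at subject variance 0
  set.seed(22)
  m <- 100; k <- 3
  id <- rep(sprintf("s%03d", 1:m), each = k)
  X <- cbind("(Intercept)" = 1, x = rnorm(m * k), z = rbinom(m * k, 1, 0.5))
  e <- rnorm(m * k, 0, 0.7)
  e <- e - rep(tapply(e, id, mean)[unique(id)], each = k)
  y <- as.numeric(X %*% c(1, 0.5, -0.3)) + e
  fit_mm <- fit_random_intercept(y, X, id)
  fit_lm <- fit_ols(y, X)
  expect_true(fit_mm$boundary)
  expect_lt(fit_mm$var_subject, 1e-8)
  expect_equal(fit_mm$coefficients$estimate, fit_lm$coefficients$estimate,
               tolerance = 1e-6)

  # iid data (no subject effect at all): estimate stays near zero
  y2 <- as.numeric(X %*% c(1, 0.5, -0.3)) + rnorm(m * k, 0, 0.7)
  fit2 <- fit_random_intercept(y2, X, id)
  expect_lt(fit2$var_subject / fit2$var_resid, 0.1)
})

test_that("REML recovers the balanced one-way closed form to 1e-6", {
  set.seed(33)
  m <- 40; k <- 4
  id <- rep(sprintf("s%02d", 1:m), each = k)
  y <- rep(rnorm(m, 0, 1.2), each = k) + rnorm(m * k, 0, 0.8) + 5
  X <- matrix(1, m * k, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_random_intercept(y, X, id)
  # ANOVA estimators for the balanced one-way layout
  ybar_i <- tapply(y, id, mean)
  msb <- k * sum((ybar_i - mean(y))^2) / (m - 1)
  msw <- sum((y - rep(ybar_i[unique(id)], each = k))^2) / (m * (k - 1))
  expect_equal(fit$var_resid, msw, tolerance = 1e-6)
  expect_equal(fit$var_subject, (msb - msw) / k, tolerance = 1e-6)
  expect_equal(fit$coefficients$estimate, mean(y), tolerance = 1e-8)
})

test_that("REML recovers simulated variance components within 10%", {
  set.seed(44)
  m <- 500; k <- 3
  id <- rep(sprintf("s%03d", 1:m), each = k)
  X <- cbind("(Intercept)" = 1, x = rnorm(m * k), g = rep(rbinom(m, 1, 0.5), each = k))
  b <- rep(rnorm(m, 0, 1.0), each = k)
  y <- as.numeric(X %*% c(2, 0.4, 0.25)) + b + rnorm(m * k, 0, 0.5)
  fit <- fit_random_intercept(y, X, id)
  expect_equal(fit$var_subject, 1.0, tolerance = 0.1)
  expect_equal(fit$var_resid, 0.25, tolerance = 0.1)
  expect_lt(abs(fit$coefficients$estimate[3] - 0.25),
            2.5 * fit$coefficients$std_error[3])
})

test_that("REML agrees with lme4 on an unbalanced longitudinal fit", {
  skip_if_not_installed("lme4")
  long <- cohort_generate(small_config(seed = 55, n_ref = 250, n_tgt = 100))
  dd <- build_design(long, model_spec("log_total", "Tgt", "Ref",
                                      longitudinal = TRUE))
  fit <- fit_random_intercept(dd$y, dd$X, dd$id)
  df <- as.data.frame(dd$X[, -1])
  names(df) <- make.names(colnames(dd$X)[-1])
  df$y <- dd$y; df$id <- dd$id
  lf <- lme4::lmer(y ~ . - id + (1 | id), data = df, REML = TRUE)
  expect_equal(unname(lme4::fixef(lf)), fit$coefficients$estimate,
               tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(vc$vcov[vc$grp == "id"], fit$var_subject, tolerance = 1e-4)
  expect_equal(vc$vcov[vc$grp == "Residual"], fit$var_resid, tolerance = 1e-4)
  se_lmer <- unname(sqrt(diag(as.matrix(vcov(lf)))))
  expect_equal(se_lmer, fit$coefficients$std_error, tolerance = 1e-4)
})

test_that("Welch t reproduces published education and BMI contrasts", {
  expect_equal(welch_t(16.31, 2.67, 7132, 15.08, 2.81, 892)$t_statistic,
               12.38, tolerance = 0.01 * 12.38)
  expect_equal(welch_t(23.90, 3.73, 283, 26.72, 5.00, 7132)$t_statistic,
               -12.30, tolerance = 0.01 * 12.30)
})

test_that("Welch t is antisymmetric, null at equality, and matches t.test", {
  w12 <- welch_t(5, 1, 30, 4, 2, 40)
  w21 <- welch_t(4, 2, 40, 5, 1, 30)
  expect_equal(w12$t_statistic, -w21$t_statistic)
  expect_equal(w12$p_value, w21$p_value)
  eq <- welch_t(3, 1, 10, 3, 1, 10)
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$p_value, 1)
  set.seed(66)
  x <- rnorm(25, 1, 2); z <- rnorm(35, 0.2, 1.3)
  ref <- t.test(x, z)
  got <- welch_t(mean(x), sd(x), 25, mean(z), sd(z), 35)
  expect_equal(got$t_statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$dof, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(welch_t(1, 0, 10, 2, 1, 10), "sd1")
  expect_error(welch_t(1, 1, 1, 2, 1, 10), "n1")
})

test_that("chi-square matches a direct expected-count oracle and its invariances", {
  oracle <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    c(stat = sum((m - e)^2 / e), dof = (nrow(m) - 1) * (ncol(m) - 1))
  }
  set.seed(77)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    m <- matrix(rpois(2 * k, 30) + 1, nrow = 2)
    got <- chi_square(m)
    want <- oracle(m)
    expect_equal(got$chi2, unname(want["stat"]), tolerance = 1e-10)
    expect_equal(got$dof, unname(want["dof"]))
    # invariant to row swap and column permutation
    expect_equal(chi_square(m[2:1, ])$chi2, got$chi2, tolerance = 1e-10)
    perm <- sample(k)
    expect_equal(chi_square(m[, perm, drop = FALSE])$chi2, got$chi2,
                 tolerance = 1e-10)
  }
  expect_equal(chi_square(matrix(c(10, 10, 10, 10), 2))$chi2, 0)
  expect_equal(chi_square(matrix(c(10, 10, 10, 10), 2))$dof, 1)
  prop_equal <- matrix(c(20, 10, 40, 20), 2)
  expect_equal(chi_square(prop_equal)$chi2, 0, tolerance = 1e-10)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("vascular source columns merge by the any-positive rule", {
  raw <- tibble::tibble(
    HYPERT = c(0, 0, NA, 1, NA),
    HXHYPER = c(0, NA, NA, 0, NA),
    HYPERTEN = c(0, 1, NA, NA, NA),
    DIABET = c(0, NA, 1, 0, NA),
    DIABETES = c(NA, 0, NA, NA, NA),
    NACCBMI = c(25, 11, 31, 75, NA)
  )
  out <- harmonize_vascular_columns(raw)
  expect_equal(out$hypertension, c(0L, 1L, NA, 1L, NA))
  expect_equal(out$diabetes, c(0L, 0L, 1L, 0L, NA))
  expect_equal(out$bmi, c(25, NA, 31, NA, NA)) # 11 and 75 out of range
  expect_false(any(c("HYPERT", "NACCBMI") %in% names(out)))
  expect_error(harmonize_vascular_columns(tibble::tibble(DIABET = 1, NACCBMI = 20)),
               "hypertension")
})
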