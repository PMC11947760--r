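test_that("generated marginals recover the group profile parameters", {
  n <- 5000
  p <- group_profile("G", n = n, age_mean = 71.36, age_sd = 9.23,
                     edu_mean = 16.31, edu_sd = 2.67, bmi_mean = 26.72,
                     bmi_sd = 5.00, male_frac = 0.47, htn_prev = 0.42,
                     dm_prev = 0.09, dx_probs = c(0.54, 0.09, 0.37))
  for (seed in 1:3) {
    cohort <- cohort_baseline(generator_config(list(p), seed = seed))
    se_p <- function(pr) sqrt(pr * (1 - pr) / n)
    expect_lt(abs(mean(cohort$age) - 71.36), 3 * 9.23 / sqrt(n))
    expect_lt(abs(sd(cohort$age) - 9.23), 3 * 9.23 / sqrt(2 * n))
    expect_lt(abs(mean(cohort$education) - 16.31), 3 * 2.67 / sqrt(n) + 0.01)
    expect_lt(abs(mean(cohort$hypertension) - 0.42), 3 * se_p(0.42))
    expect_lt(abs(mean(cohort$diabetes) - 0.09), 3 * se_p(0.09))
    expect_lt(abs(mean(cohort$sex == "male") - 0.47), 3 * se_p(0.47))
    expect_lt(abs(mean(cohort$diagnosis == "AD") - 0.37), 3 * se_p(0.37))
  }
})

test_that("degenerate noise collapses the outcome onto the linear predictor", {
  p <- group_profile("G", n = 50, age_mean = 70, age_sd = 5, edu_mean = 15,
                     edu_sd = 2, bmi_mean = 26, bmi_sd = 4, male_frac = 0.5,
                     htn_prev = 0.5, dm_prev = 0.2, dx_probs = c(1, 0, 0))
  out <- outcome_params(intercept = 9, beta_group = c(G = 0), beta_age = 0,
                        beta_edu = 0, beta_male = 0, beta_dx_mci = 0,
                        beta_dx_ad = 0, beta_htn = 0, beta_dm = 0,
                        beta_bmi = 0, sigma_subject = 0, sigma_resid = 1e-9)
  cohort <- cohort_baseline(generator_config(list(p), outcome = out, seed = 4))
  expect_equal(log(cohort$wmh_total_mm3 + 1), rep(9, 50), tolerance = 1e-6)
})

test_that("a pure direct group effect is recovered by baseline regression", {
  cfg <- generator_config(
    profiles = list(
      group_profile("A", n = 2000, age_mean = 71, age_sd = 9, edu_mean = 16,
                    edu_sd = 2.7, bmi_mean = 27, bmi_sd = 5, male_frac = 0.5,
                    htn_prev = 0.4, dm_prev = 0.1, dx_probs = c(0.6, 0.1, 0.3)),
      group_profile("B", n = 2000, age_mean = 71, age_sd = 9, edu_mean = 16,
                    edu_sd = 2.7, bmi_mean = 27, bmi_sd = 5, male_frac = 0.5,
                    htn_prev = 0.4, dm_prev = 0.1, dx_probs = c(0.6, 0.1, 0.3))
    ),
    outcome = outcome_params(beta_group = c(B = 0.3),
                             slope_time_by_group = c(A = 0, B = 0)),
    seed = 7
  )
  cohort <- cohort_baseline(cfg)
  fit <- fit_wmh_model(cohort, model_spec("log_total", "B", "A"))
  co <- dplyr::filter(tidy(fit), term == "groupB")
  expect_lt(abs(co$estimate - 0.3), 2 * co$std_error)
})

test_that("generation is deterministic under config + seed", {
  cfg <- small_config(seed = 42)
  expect_identical(cohort_baseline(cfg), cohort_baseline(cfg))
  expect_identical(cohort_generate(cfg), cohort_generate(cfg))
  cfg2 <- small_config(seed = 43)
  expect_false(identical(cohort_baseline(cfg), cohort_baseline(cfg2)))
})

test_that("invalid configuration fields are rejected by name", {
  p_args <- list(label = "G", n = 10, age_mean = 70, age_sd = 5, edu_mean = 15,
                 edu_sd = 2, bmi_mean = 26, bmi_sd = 4, male_frac = 0.5,
                 htn_prev = 0.5, dm_prev = 0.2, dx_probs = c(1, 0, 0))
  expect_error(do.call(group_profile, modifyList(p_args, list(age_sd = 0))),
               "age_sd")
  expect_error(do.call(group_profile, modifyList(p_args, list(htn_prev = 1.2))),
               "htn_prev")
  expect_error(do.call(group_profile, modifyList(p_args, list(dx_probs = c(0.5, 0.4, 0.2)))),
               "dx_probs")
  expect_error(generator_config(severity_thresholds = c(2, 1)),
               "severity_thresholds")
  expect_error(outcome_params(sigma_resid = 0), "sigma_resid")
})

test_that("education and BMI are truncated at their physical floors", {
  p <- group_profile("G", n = 3000, age_mean = 70, age_sd = 9, edu_mean = 1,
                     edu_sd = 3, bmi_mean = 14, bmi_sd = 4, male_frac = 0.5,
                     htn_prev = 0.5, dm_prev = 0.2, dx_probs = c(1, 0, 0))
  cohort <- cohort_baseline(generator_config(list(p), seed = 1))
  expect_gte(min(cohort$education), 0)
  expect_gte(min(cohort$bmi), 12)
})

test_that("longitudinal extension reproduces the visit process", {
  cfg <- small_config(seed = 10, n_ref = 3500, n_tgt = 1500)
  cohort <- cohort_generate(cfg)
  visits <- dplyr::count(cohort, id)
  expect_lt(abs(mean(visits$n) - 1.87), 0.1)
  expect_true(all(dplyr::filter(cohort, time_from_baseline_days > 0)$time_from_baseline_days >= 1))
  base <- dplyr::filter(cohort, time_from_baseline_days == 0)
  expect_equal(nrow(base), 5000)
})

test_that("zero slopes and vanishing residual noise freeze outcomes over time", {
  cfg <- small_config(seed = 3, n_ref = 80, n_tgt = 40, sigma_resid = 1e-9)
  cfg$outcome$slope_time_by_group[] <- 0
  cohort <- cohort_generate(cfg)
  spread <- cohort |>
    dplyr::mutate(y = log(wmh_total_mm3 + 1)) |>
    dplyr::group_by(id) |>
    dplyr::summarise(d = diff(range(y)))
  expect_lt(max(spread$d), 1e-6)
})

test_that("a group-specific progression slope is recovered by the interaction model", {
  cfg <- small_config(seed = 8, n_ref = 1200, n_tgt = 1200,
                      direct = 0, sigma_subject = 0.3, sigma_resid = 0.3)
  cfg$outcome$slope_time_by_group <- c(Ref = 0, Tgt = 0.05)
  cfg$n_visits_mean <- 3
  cohort <- cohort_generate(cfg)
  fit <- fit_wmh_model(cohort, model_spec("log_total", "Tgt", "Ref",
                                          longitudinal = TRUE, interaction = TRUE))
  co <- dplyr::filter(tidy(fit), term == "groupTgt:time_years")
  expect_lt(abs(co$estimate - 0.05), 2 * co$std_error)
})

test_that("longitudinal extension refuses duplicated participant ids", {
  cfg <- small_config(seed = 2, n_ref = 20, n_tgt = 10)
  base <- cohort_baseline(cfg)
  expect_error(cohort_longitudinal(dplyr::bind_rows(base, base[1, ]), cfg),
               "duplicate")
})

test_that("severity staging is monotone with inclusive lower bounds", {
  th <- c(2, 5)
  expect_identical(severity_from_volume(2 - 1e-9, th), 0L)
  expect_identical(severity_from_volume(2, th), 1L)
  expect_identical(severity_from_volume(5, th), 2L)
  expect_identical(severity_from_volume(c(-10, 3, 100), th), c(0L, 1L, 2L))
  x <- sort(rnorm(100, 3, 3))
  expect_true(all(diff(severity_from_volume(x, th)) >= 0))
  expect_error(severity_from_volume(1, c(5, 2)), "increasing")
  expect_error(severity_from_volume(1, c(2, 2)), "increasing")
})

test_that("thresholds at empirical quantiles produce the expected severity mix", {
  set.seed(5)
  y <- rnorm(10000, 9, 1)
  th <- quantile(y, c(0.6, 0.9), type = 7)
  sev <- severity_from_volume(y, th)
  mix <- as.numeric(prop.table(table(factor(sev, levels = 0:2))))
  expect_equal(mix, c(0.6, 0.3, 0.1), tolerance = 0.01)
})

test_that("default severity thresholds give roughly a 52/28/20 mix", {
  cohort <- cohort_baseline(generator_config(clinical_cohort_profiles(scale = 0.5),
                                             seed = 6))
  mix <- as.numeric(prop.table(table(factor(cohort$wmh_severity, levels = 0:2))))
  expect_equal(mix, c(0.52, 0.28, 0.20), tolerance = 0.04)
})

test_that("cohort summaries reproduce the generating profile", {
  cohort <- cohort_baseline(generator_config(clinical_cohort_profiles(scale = 0.7),
                                             seed = 9))
  s <- summarize_cohort(cohort)
  w_age <- dplyr::filter(s, group == "White", variable == "age")
  expect_equal(w_age$mean, 71.36, tolerance = 3 * 9.23 / sqrt(4992))
  expect_equal(w_age$sd, 9.23, tolerance = 0.3)
  w_htn <- dplyr::filter(s, group == "White", variable == "hypertension",
                         level == "yes")
  expect_equal(w_htn$pct / 100, 2990 / 7132, tolerance = 0.025)
  b_dx <- dplyr::filter(s, group == "Black", variable == "diagnosis")
  expect_equal(sum(b_dx$count), dplyr::filter(s, group == "Black", variable == "age")$n)
})

test_that("cohort summaries guard degenerate groups and missing columns", {
  single <- toy_cohort(n = 2)
  single$group <- c("A", "B")
  s <- summarize_cohort(single)
  expect_true(all(is.na(dplyr::filter(s, variable == "age")$sd)))
  expect_error(summarize_cohort(dplyr::select(toy_cohort(), -diagnosis)),
               "diagnosis")
  two <- toy_cohort(n = 10)
  two$group <- rep("A", 10)
  twin <- dplyr::mutate(two, group = "B", id = paste0(id, "b"))
  s2 <- summarize_cohort(dplyr::bind_rows(two, twin))
  a <- dplyr::filter(s2, group == "A") |> dplyr::select(-group)
  b <- dplyr::filter(s2, group == "B") |> dplyr::select(-group)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("vascular mediation structure appears unadjusted and vanishes adjusted", {
  cfg <- generator_config(
    profiles = list(
      group_profile("A", n = 5000, age_mean = 71, age_sd = 9, edu_mean = 16,
                    edu_sd = 2.7, bmi_mean = 26.5, bmi_sd = 5, male_frac = 0.45,
                    htn_prev = 0.30, dm_prev = 0.08, dx_probs = c(0.6, 0.1, 0.3)),
      group_profile("B", n = 5000, age_mean = 71, age_sd = 9, edu_mean = 16,
                    edu_sd = 2.7, bmi_mean = 29.5, bmi_sd = 5, male_frac = 0.45,
                    htn_prev = 0.70, dm_prev = 0.35, dx_probs = c(0.6, 0.1, 0.3))
    ),
    outcome = outcome_params(beta_group = c(B = 0), beta_htn = 0.5,
                             beta_dm = 0.5, beta_bmi = 0.02,
                             slope_time_by_group = c(A = 0, B = 0)),
    seed = 12
  )
  cohort <- cohort_baseline(cfg)
  mediated <- 0.40 * 0.5 + 0.27 * 0.5 + 3 * 0.02
  un <- dplyr::filter(tidy(fit_wmh_model(cohort, model_spec("log_total", "B", "A"))),
                      term == "groupB")
  ad <- dplyr::filter(tidy(fit_wmh_model(cohort, model_spec("log_total", "B", "A",
                                                            covariates = "vascular"))),
                      term == "groupB")
  expect_lt(abs(un$estimate - mediated), 3 * un$std_error)
  expect_gt(un$t_statistic, 4)                  # clearly nonzero unadjusted
  expect_lt(abs(ad$estimate), 3 * ad$std_error) # zero once adjusted
})

test_that("regional volumes track the total through the region weights", {
  cohort <- small_cohort(seed = 21, n_ref = 1500, n_tgt = 500)
  lt <- log(cohort$wmh_total_mm3 + 1)
  lf <- log(cohort$wmh_frontal_mm3 + 1)
  expect_equal(mean(lf - lt), log(0.58), tolerance = 0.02)
  expect_equal(sd(lf - lt), 0.1, tolerance = 0.02)
  expect_lt(cor(lf, lt), 1)
  expect_gt(cor(lf, lt), 0.98)
})

test_that("generator configs round-trip through YAML", {
  cfg <- small_config(seed = 77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  cfg2 <- read_generator_config(path)
  expect_equal(cfg2$outcome$beta_group, cfg$outcome$beta_group)
  expect_equal(cfg2$severity_thresholds, cfg$severity_thresholds)
  expect_equal(cfg2$profiles$Tgt$dx_probs, cfg$profiles$Tgt$dx_probs)
  expect_identical(cohort_baseline(cfg2), cohort_baseline(cfg))
})
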