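# Small fixtures shared across test files. Everything is generated in code.

# A compact two-group configuration that runs fast.
small_config <- function(seed = 1L, n_ref = 600, n_tgt = 200, direct = 0.3,
                         sigma_subject = 0.4, sigma_resid = 0.5) {
  generator_config(
    profiles = list(
      group_profile("Ref", n = n_ref, age_mean = 71, age_sd = 9,
                    edu_mean = 16, edu_sd = 2.7, bmi_mean = 27, bmi_sd = 5,
                    male_frac = 0.47, htn_prev = 0.4, dm_prev = 0.1,
                    dx_probs = c(0.55, 0.10, 0.35)),
      group_profile("Tgt", n = n_tgt, age_mean = 72, age_sd = 9,
                    edu_mean = 15, edu_sd = 2.8, bmi_mean = 29, bmi_sd = 6,
                    male_frac = 0.30, htn_prev = 0.65, dm_prev = 0.25,
                    dx_probs = c(0.60, 0.12, 0.28))
    ),
    outcome = outcome_params(
      beta_group = c(Tgt = direct),
      slope_time_by_group = c(Ref = 0.08, Tgt = 0.10),
      sigma_subject = sigma_subject, sigma_resid = sigma_resid
    ),
    seed = seed
  )
}

small_cohort <- function(seed = 1L, ...) cohort_baseline(small_config(seed = seed, ...))

# Hand-rolled cohort table with exact values, for deterministic checks.
toy_cohort <- function(n = 12, seed = 99) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("P%02d", seq_len(n)),
    group = rep(c("A", "B"), length.out = n),
    ethnicity = "Non-Hispanic",
    age = seq(60, 82, length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    education = round(seq(12, 20, length.out = n), 1),
    diagnosis = rep(c("NC", "MCI", "AD"), length.out = n),
    bmi = seq(22, 33, length.out = n),
    hypertension = rep(c(0L, 1L), length.out = n),
    diabetes = rep(c(0L, 0L, 1L), length.out = n),
    time_from_baseline_days = 0,
    wmh_severity = rep(0:2, length.out = n),
    wmh_total_mm3 = exp(seq(8, 10, length.out = n)) - 1,
    wmh_frontal_mm3 = exp(seq(7.5, 9.5, length.out = n)) - 1,
    wmh_parietal_mm3 = exp(seq(7, 9, length.out = n)) - 1,
    wmh_temporal_mm3 = exp(seq(5, 7, length.out = n)) - 1,
    wmh_occipital_mm3 = exp(seq(4.5, 6.5, length.out = n)) - 1
  )
}

# Independent OLS oracle: Moore-Penrose pseudo-inverse via SVD.
pinv_ols <- function(y, X) {
  s <- svd(X)
  tol <- max(dim(X)) * max(s$d) * .Machine$double.eps
  d_inv <- ifelse(s$d > tol, 1 / s$d, 0)
  as.numeric(s$v %*% (d_inv * crossprod(s$u, y)))
}
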