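# Synthetic cohort generator.
#
# Emulates the statistical structure of a large multi-site clinical/MRI aging
# cohort (NACC-like): per-group demographic and vascular-risk marginals, a
# linear outcome model on the log lesion-volume scale with a subject random
# intercept, group-specific annual progression slopes, and an ordinal
# severity staging of the volumetric burden.

#' Define the marginal structure of one demographic group
#'
#' A `group_profile` holds the sampling distributions used to draw
#' participants of one group: normal age/education/BMI margins, Bernoulli
#' sex/hypertension/diabetes margins, and a categorical diagnosis mix
#' (NC/MCI/AD).
#'
#' @param label Group name (e.g. `"White"`). Used as the `group` column value.
#' @param n Number of participants to generate.
#' @param age_mean,age_sd Age distribution, years.
#' @param edu_mean,edu_sd Education distribution, years (truncated at 0).
#' @param bmi_mean,bmi_sd Body mass index, kg/m2 (truncated at 12).
#' @param male_frac Proportion of male participants.
#' @param htn_prev,dm_prev Hypertension and diabetes prevalence.
#' @param dx_probs Length-3 probability vector for diagnoses NC, MCI, AD.
#' @param ethnicity Ethnicity label attached to every participant of the
#'   group; defaults to `"Non-Hispanic"` unless the group label itself is
#'   `"Hispanic"`.
#' @return An object of class `group_profile`.
#' @export
#' @examples
#' group_profile("Black", n = 892, age_mean = 72.26, age_sd = 8.82,
#'               edu_mean = 15.08, edu_sd = 2.81, bmi_mean = 29.13,
#'               bmi_sd = 6.04, male_frac = 0.27, htn_prev = 0.70,
#'               dm_prev = 0.27, dx_probs = c(549, 95, 248) / 892)
group_profile <- function(label, n, age_mean, age_sd, edu_mean, edu_sd,
                          bmi_mean, bmi_sd, male_frac, htn_prev, dm_prev,
                          dx_probs,
                          ethnicity = if (identical(label, "Hispanic")) "Hispanic" else "Non-Hispanic") {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    abort_field("label", "must be a non-empty string")
  }
  check_number(n, "n", lower = 1)
  check_number(age_mean, "age_mean")
  check_number(age_sd, "age_sd", lower = 0, strict_lower = TRUE)
  check_number(edu_mean, "edu_mean")
  check_number(edu_sd, "edu_sd", lower = 0, strict_lower = TRUE)
  check_number(bmi_mean, "bmi_mean")
  check_number(bmi_sd, "bmi_sd", lower = 0, strict_lower = TRUE)
  check_prop(male_frac, "male_frac")
  check_prop(htn_prev, "htn_prev")
  check_prop(dm_prev, "dm_prev")
  if (!is.numeric(dx_probs) || length(dx_probs) != 3L || any(dx_probs < 0)) {
    abort_field("dx_probs", "must be 3 non-negative probabilities (NC, MCI, AD)")
  }
  if (abs(sum(dx_probs) - 1) > 1e-9) {
    abort_field("dx_probs", "must sum to 1")
  }
  structure(
    list(label = label, n = as.integer(n),
         age_mean = age_mean, age_sd = age_sd,
         edu_mean = edu_mean, edu_sd = edu_sd,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd,
         male_frac = male_frac, htn_prev = htn_prev, dm_prev = dm_prev,
         dx_probs = as.numeric(dx_probs), ethnicity = ethnicity),
    class = "group_profile"
  )
}

#' Outcome model parameters on the log lesion-volume scale
#'
#' The generative outcome model is, for participant i of group g at time t
#' (years from baseline):
#'
#' `log(WMH_total + 1) = intercept + beta_group[g] + beta_age * age +
#'  beta_edu * education + beta_male * male + beta_dx_mci * MCI +
#'  beta_dx_ad * AD + beta_htn * HTN + beta_dm * DM + beta_bmi * BMI +
#'  slope_time_by_group[g] * t + b_i + e_it`
#'
#' with `b_i ~ N(0, sigma_subject^2)` and `e_it ~ N(0, sigma_resid^2)`.
#' Regional volumes are apportioned from the total via `region_weights` plus
#' independent log-scale noise.
#'
#' @param intercept Intercept, log(mm3 + 1) scale.
#' @param beta_group Named numeric vector of direct group effects (groups not
#'   named get 0).
#' @param beta_age,beta_edu,beta_bmi Per-unit slopes.
#' @param beta_male,beta_dx_mci,beta_dx_ad,beta_htn,beta_dm Additive offsets.
#' @param slope_time_by_group Named numeric vector of annual change per group
#'   (log scale per year; groups not named get 0).
#' @param sigma_subject Subject random-intercept SD (>= 0).
#' @param sigma_resid Residual SD (> 0).
#' @param region_weights Named non-negative weights for frontal, parietal,
#'   temporal, occipital apportionment of the total volume.
#' @param region_noise_sd SD of the independent log-scale regional noise.
#' @return An object of class `outcome_params`.
#' @export
outcome_params <- function(intercept = 5.7,
                           beta_group = c(Black = 0.23, Asian = 0, Hispanic = -0.13),
                           beta_age = 0.04, beta_edu = -0.01, beta_male = 0.10,
                           beta_dx_mci = 0.20, beta_dx_ad = 0.35,
                           beta_htn = 0.20, beta_dm = 0.15, beta_bmi = 0.008,
                           slope_time_by_group = c(White = 0.08, Black = 0.10,
                                                   Asian = 0.02, Hispanic = 0.06),
                           sigma_subject = 0.5, sigma_resid = 0.6,
                           region_weights = c(frontal = 0.58, parietal = 0.33,
                                              temporal = 0.05, occipital = 0.04),
                           region_noise_sd = 0.1) {
  check_number(intercept, "intercept")
  for (f in c("beta_age", "beta_edu", "beta_male", "beta_dx_mci", "beta_dx_ad",
              "beta_htn", "beta_dm", "beta_bmi")) {
    check_number(get(f), f)
  }
  check_number(sigma_subject, "sigma_subject", lower = 0)
  check_number(sigma_resid, "sigma_resid", lower = 0, strict_lower = TRUE)
  check_number(region_noise_sd, "region_noise_sd", lower = 0)
  if (!is.numeric(beta_group) || (length(beta_group) > 0 && is.null(names(beta_group)))) {
    abort_field("beta_group", "must be a named numeric vector")
  }
  if (!is.numeric(slope_time_by_group) ||
      (length(slope_time_by_group) > 0 && is.null(names(slope_time_by_group)))) {
    abort_field("slope_time_by_group", "must be a named numeric vector")
  }
  need_regions <- c("frontal", "parietal", "temporal", "occipital")
  if (!is.numeric(region_weights) || !all(need_regions %in% names(region_weights))) {
    abort_field("region_weights", "must be named weights for frontal, parietal, temporal, occipital")
  }
  if (any(region_weights < 0)) abort_field("region_weights", "must be non-negative")
  structure(
    list(intercept = intercept, beta_group = beta_group,
         beta_age = beta_age, beta_edu = beta_edu, beta_male = beta_male,
         beta_dx_mci = beta_dx_mci, beta_dx_ad = beta_dx_ad,
         beta_htn = beta_htn, beta_dm = beta_dm, beta_bmi = beta_bmi,
         slope_time_by_group = slope_time_by_group,
         sigma_subject = sigma_subject, sigma_resid = sigma_resid,
         region_weights = region_weights[need_regions],
         region_noise_sd = region_noise_sd),
    class = "outcome_params"
  )
}

#' Assemble a full generator configuration
#'
#' @param profiles List of [group_profile()] objects (labels must be unique).
#' @param outcome An [outcome_params()] object.
#' @param n_visits_mean Expected number of repeated assessments per
#'   participant (>= 1); visit counts are drawn as
#'   `1 + Poisson(n_visits_mean - 1)`.
#' @param visit_interval_mean,visit_interval_sd Inter-visit interval, days;
#'   draws are floored at 1 day.
#' @param severity_thresholds Strictly increasing length-2 cutpoints on the
#'   `log(total + 1)` scale separating low/moderate/extensive severity.
#' @param seed Integer seed making generation reproducible.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(profiles = clinical_cohort_profiles(),
                             outcome = outcome_params(),
                             n_visits_mean = 1.87,
                             visit_interval_mean = 455,
                             visit_interval_sd = 160,
                             severity_thresholds = c(8.97, 9.70),
                             seed = 1L) {
  if (inherits(profiles, "group_profile")) profiles <- list(profiles)
  if (!length(profiles) || !all(vapply(profiles, inherits, TRUE, "group_profile"))) {
    abort_field("profiles", "must be a list of group_profile objects")
  }
  labels <- vapply(profiles, `[[`, "", "label")
  if (anyDuplicated(labels)) abort_field("profiles", "group labels must be unique")
  if (!inherits(outcome, "outcome_params")) {
    abort_field("outcome", "must be an outcome_params object")
  }
  check_number(n_visits_mean, "n_visits_mean", lower = 1)
  check_number(visit_interval_mean, "visit_interval_mean", lower = 0, strict_lower = TRUE)
  check_number(visit_interval_sd, "visit_interval_sd", lower = 0)
  if (!is.numeric(severity_thresholds) || length(severity_thresholds) != 2L ||
      diff(severity_thresholds) <= 0) {
    abort_field("severity_thresholds", "must be 2 strictly increasing cutpoints")
  }
  check_number(seed, "seed")
  structure(
    list(profiles = stats::setNames(profiles, labels), outcome = outcome,
         n_visits_mean = n_visits_mean,
         visit_interval_mean = visit_interval_mean,
         visit_interval_sd = visit_interval_sd,
         severity_thresholds = as.numeric(severity_thresholds),
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Default group profiles for the clinical (visually staged) cohort
#'
#' Group margins follow the published descriptive statistics of the NACC
#' clinical sample with visual WMH staging: 7132 White, 892 Black, 283 Asian
#' and 661 Hispanic participants, with the corresponding age, education, BMI,
#' sex, diagnosis, hypertension and diabetes margins. Diagnosis mixes use the
#' reported participant counts.
#'
#' @param scale Optional factor applied to every group size (rounded, floored
#'   at 2) to generate smaller cohorts with identical structure.
#' @return List of [group_profile()] objects.
#' @export
clinical_cohort_profiles <- function(scale = 1) {
  check_number(scale, "scale", lower = 0, strict_lower = TRUE)
  n <- function(k) max(2L, as.integer(round(k * scale)))
  name_profiles(list(
    group_profile("White", n = n(7132), age_mean = 71.36, age_sd = 9.23,
                  edu_mean = 16.31, edu_sd = 2.67, bmi_mean = 26.72, bmi_sd = 5.00,
                  male_frac = 3364 / 7132, htn_prev = 2990 / 7132, dm_prev = 665 / 7132,
                  dx_probs = c(3869, 656, 2607) / 7132),
    group_profile("Black", n = n(892), age_mean = 72.26, age_sd = 8.82,
                  edu_mean = 15.08, edu_sd = 2.81, bmi_mean = 29.13, bmi_sd = 6.04,
                  male_frac = 244 / 892, htn_prev = 625 / 892, dm_prev = 239 / 892,
                  dx_probs = c(549, 95, 248) / 892),
    group_profile("Asian", n = n(283), age_mean = 71.27, age_sd = 9.53,
                  edu_mean = 16.48, edu_sd = 3.13, bmi_mean = 23.90, bmi_sd = 3.73,
                  male_frac = 116 / 283, htn_prev = 131 / 283, dm_prev = 50 / 283,
                  dx_probs = c(167, 28, 88) / 283),
    group_profile("Hispanic", n = n(661), age_mean = 71.47, age_sd = 8.66,
                  edu_mean = 13.61, edu_sd = 4.54, bmi_mean = 28.09, bmi_sd = 5.04,
                  male_frac = 236 / 661, htn_prev = 374 / 661, dm_prev = 167 / 661,
                  dx_probs = c(301, 130, 230) / 661)
  ))
}

#' Default group profiles for the volumetric MRI subset
#'
#' Margins follow the published descriptive statistics of the NACC MRI
#' subset (1876 White, 260 Black, 55 Asian, 207 Hispanic participants).
#'
#' @inheritParams clinical_cohort_profiles
#' @return List of [group_profile()] objects.
#' @export
mri_cohort_profiles <- function(scale = 1) {
  check_number(scale, "scale", lower = 0, strict_lower = TRUE)
  n <- function(k) max(2L, as.integer(round(k * scale)))
  name_profiles(list(
    group_profile("White", n = n(1876), age_mean = 70.38, age_sd = 9.06,
                  edu_mean = 15.93, edu_sd = 2.85, bmi_mean = 26.77, bmi_sd = 4.71,
                  male_frac = 869 / 1876, htn_prev = 779 / 1876, dm_prev = 180 / 1876,
                  dx_probs = c(1098, 176, 602) / 1876),
    group_profile("Black", n = n(260), age_mean = 70.98, age_sd = 9.12,
                  edu_mean = 14.53, edu_sd = 3.09, bmi_mean = 29.73, bmi_sd = 5.49,
                  male_frac = 75 / 260, htn_prev = 181 / 260, dm_prev = 94 / 260,
                  dx_probs = c(181, 37, 42) / 260),
    group_profile("Asian", n = n(55), age_mean = 74.80, age_sd = 9.60,
                  edu_mean = 15.62, edu_sd = 3.03, bmi_mean = 23.62, bmi_sd = 2.95,
                  male_frac = 19 / 55, htn_prev = 31 / 55, dm_prev = 14 / 55,
                  dx_probs = c(30, 8, 17) / 55),
    group_profile("Hispanic", n = n(207), age_mean = 72.32, age_sd = 7.76,
                  edu_mean = 11.25, edu_sd = 4.88, bmi_mean = 28.93, bmi_sd = 5.33,
                  male_frac = 66 / 207, htn_prev = 129 / 207, dm_prev = 61 / 207,
                  dx_probs = c(131, 17, 59) / 207)
  ))
}

name_profiles <- function(profiles) {
  stats::setNames(profiles, vapply(profiles, `[[`, "", "label"))
}

# Linear predictor of the outcome model at time 0 for rows of a cohort table.
linear_predictor <- function(outcome, data) {
  bg <- outcome$beta_group
  g_eff <- ifelse(data$group %in% names(bg), bg[data$group], 0)
  outcome$intercept + as.numeric(g_eff) +
    outcome$beta_age * data$age +
    outcome$beta_edu * data$education +
    outcome$beta_male * (data$sex == "male") +
    outcome$beta_dx_mci * (data$diagnosis == "MCI") +
    outcome$beta_dx_ad * (data$diagnosis == "AD") +
    outcome$beta_htn * data$hypertension +
    outcome$beta_dm * data$diabetes +
    outcome$beta_bmi * data$bmi
}

group_slope <- function(outcome, group) {
  sl <- outcome$slope_time_by_group
  as.numeric(ifelse(group %in% names(sl), sl[group], 0))
}

# Volumes (total + regional) and severity from a latent log(total + 1) value.
volumes_from_latent <- function(y, outcome, thresholds) {
  w <- outcome$region_weights
  reg <- lapply(names(w), function(r) {
    lr <- log(w[[r]]) + y + stats::rnorm(length(y), 0, outcome$region_noise_sd)
    pmax(exp(lr) - 1, 0)
  })
  names(reg) <- paste0("wmh_", names(w), "_mm3")
  c(list(wmh_severity = severity_from_volume(y, thresholds),
         wmh_total_mm3 = pmax(exp(y) - 1, 0)),
    reg)
}

#' Generate a baseline (one row per participant) synthetic cohort
#'
#' Draws demographics, vascular factors and diagnosis from each group
#' profile, then the log-scale total WMH outcome from the linear outcome
#' model plus subject intercept and residual. Regional volumes are
#' apportioned from the total; ordinal severity is staged from the log total
#' via the configured cutpoints.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per participant and the standard cohort
#'   columns (`id`, `group`, `ethnicity`, demographics, vascular factors,
#'   `time_from_baseline_days = 0`, severity and volumes).
#' @export
#' @examples
#' cohort <- cohort_baseline(generator_config(clinical_cohort_profiles(scale = 0.02)))
#' dplyr::count(cohort, group)
cohort_baseline <- function(config) {
  if (!inherits(config, "generator_config")) {
    abort_field("config", "must be a generator_config object")
  }
  set.seed(config$seed)
  out <- config$outcome
  pieces <- lapply(config$profiles, function(p) {
    n <- p$n
    tibble::tibble(
      id = sprintf("%s-%05d", p$label, seq_len(n)),
      group = p$label,
      ethnicity = p$ethnicity,
      age = stats::rnorm(n, p$age_mean, p$age_sd),
      sex = ifelse(stats::runif(n) < p$male_frac, "male", "female"),
      education = pmax(stats::rnorm(n, p$edu_mean, p$edu_sd), 0),
      diagnosis = sample(c("NC", "MCI", "AD"), n, replace = TRUE, prob = p$dx_probs),
      bmi = pmax(stats::rnorm(n, p$bmi_mean, p$bmi_sd), 12),
      hypertension = as.integer(stats::runif(n) < p$htn_prev),
      diabetes = as.integer(stats::runif(n) < p$dm_prev),
      time_from_baseline_days = 0
    )
  })
  cohort <- dplyr::bind_rows(pieces)
  lp <- linear_predictor(out, cohort)
  y <- lp + stats::rnorm(nrow(cohort), 0, out$sigma_subject) +
    stats::rnorm(nrow(cohort), 0, out$sigma_resid)
  vols <- volumes_from_latent(y, out, config$severity_thresholds)
  dplyr::bind_cols(cohort, tibble::as_tibble(vols))
}

#' Extend a baseline cohort with longitudinal follow-up visits
#'
#' Per participant, a visit count is drawn as `1 + Poisson(n_visits_mean -
#' 1)` and inter-visit intervals as normal draws floored at 1 day. Follow-up
#' outcomes share the participant's subject intercept, add the group-specific
#' annual slope (intervals are converted to years by /365.25), and receive a
#' fresh residual at each visit. The subject intercept is recovered from the
#' baseline outcome by its conditional normal distribution given the baseline
#' deviation from the linear predictor, so any schema-complete baseline table
#' can be extended.
#'
#' @param baseline Baseline cohort (one row per participant), e.g. from
#'   [cohort_baseline()].
#' @param config The same [generator_config()] used to generate the baseline.
#' @return A tibble with one row per participant-visit, baseline rows having
#'   `time_from_baseline_days = 0`.
#' @export
cohort_longitudinal <- function(baseline, config) {
  if (!inherits(config, "generator_config")) {
    abort_field("config", "must be a generator_config object")
  }
  check_cohort(baseline)
  if (anyDuplicated(baseline$id)) {
    rlang::abort("duplicate participant identifiers in baseline table",
                 class = "wmhboot_schema_error")
  }
  set.seed(iteration_seed(config$seed, 104729L)) # distinct stream from baseline draw
  out <- config$outcome
  n <- nrow(baseline)

  lp0 <- linear_predictor(out, baseline)
  y0 <- log(baseline$wmh_total_mm3 + 1)
  s <- y0 - lp0
  v_b <- out$sigma_subject^2
  v_e <- out$sigma_resid^2
  rho <- if (v_b + v_e > 0) v_b / (v_b + v_e) else 0
  b <- stats::rnorm(n, rho * s, sqrt(rho * v_e)) # b | y0, conditional normal

  n_extra <- stats::rpois(n, config$n_visits_mean - 1)
  slope <- group_slope(out, baseline$group)

  idx <- rep.int(seq_len(n), n_extra)
  if (length(idx) == 0L) {
    return(dplyr::arrange(baseline, .data$id, .data$time_from_baseline_days))
  }
  gaps <- pmax(round(stats::rnorm(length(idx), config$visit_interval_mean,
                                  config$visit_interval_sd)), 1)
  visit_days <- stats::ave(gaps, idx, FUN = cumsum)

  fu <- baseline[idx, ]
  fu$time_from_baseline_days <- visit_days
  years <- visit_days / 365.25
  y_fu <- lp0[idx] + slope[idx] * years + b[idx] +
    stats::rnorm(length(idx), 0, out$sigma_resid)
  vols <- volumes_from_latent(y_fu, out, config$severity_thresholds)
  for (colname in names(vols)) fu[[colname]] <- vols[[colname]]

  dplyr::arrange(dplyr::bind_rows(baseline, fu), .data$id, .data$time_from_baseline_days)
}

#' Generate a full longitudinal cohort in one call
#'
#' Convenience wrapper: [cohort_baseline()] followed by
#' [cohort_longitudinal()].
#'
#' @inheritParams cohort_baseline
#' @return A participant-visit tibble.
#' @export
cohort_generate <- function(config) {
  cohort_longitudinal(cohort_baseline(config), config)
}

#' Stage ordinal severity from a log-scale volume
#'
#' Maps a `log(volume + 1)` value to ordinal severity 0 (low), 1 (moderate)
#' or 2 (extensive) using two strictly increasing cutpoints. The lower bound
#' of each class is inclusive: a value exactly at a cutpoint takes the higher
#' class.
#'
#' @param log_volume Numeric vector of log-scale volumes.
#' @param thresholds Strictly increasing length-2 numeric cutpoints.
#' @return Integer vector in `{0, 1, 2}`.
#' @export
#' @examples
#' severity_from_volume(c(8, 9.2, 11), thresholds = c(8.97, 9.70))
severity_from_volume <- function(log_volume, thresholds) {
  if (!is.numeric(thresholds) || length(thresholds) != 2L || diff(thresholds) <= 0) {
    rlang::abort("`thresholds` must be 2 strictly increasing cutpoints",
                 class = "wmhboot_config_error")
  }
  findInterval(log_volume, thresholds)
}

#' Descriptive summary of a cohort, one row per group and variable
#'
#' Baseline rows only. Continuous variables (age, education, BMI) are
#' summarised as mean and SD; binary/categorical variables (sex, diagnosis,
#' hypertension, diabetes) as count and percentage. SDs of single-participant
#' groups are reported as `NA`.
#'
#' @param cohort A participant-visit cohort table.
#' @param by Grouping column, `"group"` (default) or `"ethnicity"`.
#' @return A tibble with columns `group`, `variable`, `level`, `n`, `mean`,
#'   `sd`, `count`, `pct`.
#' @export
summarize_cohort <- function(cohort, by = "group") {
  check_cohort(cohort)
  if (!by %in% c("group", "ethnicity")) abort_field("by", "must be 'group' or 'ethnicity'")
  base <- baseline_rows(cohort)
  if (nrow(base) == 0L) rlang::abort("cohort has no baseline rows", class = "wmhboot_schema_error")
  base$.g <- base[[by]]

  cont <- base |>
    dplyr::group_by(.data$.g) |>
    dplyr::summarise(dplyr::across(c("age", "education", "bmi"),
                                   list(mean = mean, sd = stats::sd)),
                     n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_longer(-c(".g", "n"), names_to = c("variable", ".value"),
                        names_sep = "_(?=mean$|sd$)") |>
    dplyr::mutate(level = NA_character_, count = NA_integer_, pct = NA_real_)

  cat_long <- base |>
    dplyr::mutate(sex = as.character(.data$sex),
                  diagnosis = as.character(.data$diagnosis),
                  hypertension = ifelse(.data$hypertension == 1, "yes", "no"),
                  diabetes = ifelse(.data$diabetes == 1, "yes", "no")) |>
    tidyr::pivot_longer(c("sex", "diagnosis", "hypertension", "diabetes"),
                        names_to = "variable", values_to = "level") |>
    dplyr::count(.data$.g, .data$variable, .data$level, name = "count") |>
    dplyr::group_by(.data$.g, .data$variable) |>
    dplyr::mutate(n = sum(.data$count), pct = 100 * .data$count / .data$n) |>
    dplyr::ungroup() |>
    dplyr::mutate(mean = NA_real_, sd = NA_real_)

  dplyr::bind_rows(cont, cat_long) |>
    dplyr::rename(group = ".g") |>
    dplyr::select("group", "variable", "level", "n", "mean", "sd", "count", "pct") |>
    dplyr::arrange(.data$group, .data$variable, .data$level)
}

#' Write / read a generator configuration as YAML
#'
#' @param config A [generator_config()].
#' @param path File path.
#' @return `read_generator_config()` returns a [generator_config()];
#'   `write_generator_config()` returns `path` invisibly.
#' @export
write_generator_config <- function(config, path) {
  if (!inherits(config, "generator_config")) {
    abort_field("config", "must be a generator_config object")
  }
  x <- list(
    profiles = lapply(unname(config$profiles), function(p) unclass(p)),
    outcome = lapply(unclass(config$outcome), function(v) {
      if (!is.null(names(v))) as.list(v) else v
    }),
    n_visits_mean = config$n_visits_mean,
    visit_interval_mean = config$visit_interval_mean,
    visit_interval_sd = config$visit_interval_sd,
    severity_thresholds = config$severity_thresholds,
    seed = config$seed
  )
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  profiles <- lapply(x$profiles, function(p) {
    group_profile(p$label, n = p$n, age_mean = p$age_mean, age_sd = p$age_sd,
                  edu_mean = p$edu_mean, edu_sd = p$edu_sd,
                  bmi_mean = p$bmi_mean, bmi_sd = p$bmi_sd,
                  male_frac = p$male_frac, htn_prev = p$htn_prev,
                  dm_prev = p$dm_prev, dx_probs = unlist(p$dx_probs),
                  ethnicity = p$ethnicity)
  })
  o <- x$outcome
  outcome <- outcome_params(
    intercept = o$intercept,
    beta_group = unlist(o$beta_group) %||% numeric(),
    beta_age = o$beta_age, beta_edu = o$beta_edu, beta_male = o$beta_male,
    beta_dx_mci = o$beta_dx_mci, beta_dx_ad = o$beta_dx_ad,
    beta_htn = o$beta_htn, beta_dm = o$beta_dm, beta_bmi = o$beta_bmi,
    slope_time_by_group = unlist(o$slope_time_by_group) %||% numeric(),
    sigma_subject = o$sigma_subject, sigma_resid = o$sigma_resid,
    region_weights = unlist(o$region_weights),
    region_noise_sd = o$region_noise_sd
  )
  generator_config(profiles = profiles, outcome = outcome,
                   n_visits_mean = x$n_visits_mean,
                   visit_interval_mean = x$visit_interval_mean,
                   visit_interval_sd = x$visit_interval_sd,
                   severity_thresholds = unlist(x$severity_thresholds),
                   seed = x$seed)
}
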