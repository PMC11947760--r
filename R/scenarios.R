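# Canned generator configurations for the three causal structures the
# pipeline is designed to detect: vascular mediation (attenuation),
# vascular suppression (masking), and a pure null.

#' Mediation scenario: group contrast partly carried by vascular factors
#'
#' Two groups at the reference/target sizes of the clinical cohort (7132 vs
#' 892). The target group has higher hypertension/diabetes prevalence and
#' BMI, all of which raise log-WMH, plus an optional direct group effect.
#' Adjusting for the vascular factors should attenuate the group contrast
#' toward the direct effect.
#'
#' @param direct Direct group effect on the log-volume scale (default 0.10).
#' @param seed Generator seed.
#' @param scale Optional size scaling passed to [clinical_cohort_profiles()].
#' @return A [generator_config()].
#' @export
config_mediation <- function(direct = 0.10, seed = 1L, scale = 1) {
  profiles <- clinical_cohort_profiles(scale = scale)[c("White", "Black")]
  generator_config(
    profiles = profiles,
    outcome = outcome_params(beta_group = c(Black = direct),
                             slope_time_by_group = c(White = 0.08, Black = 0.10)),
    seed = seed
  )
}

#' Suppression scenario: negative direct effect masked by vascular factors
#'
#' Mirrors the Hispanic vs non-Hispanic contrast structure: the target group
#' has a negative direct effect on log-WMH that is cancelled in expectation
#' by a positive vascular-mediated path (much higher hypertension/diabetes
#' prevalence and BMI). Unadjusted, the group contrast is near zero;
#' adjusting for vascular factors reveals the negative direct effect.
#'
#' The direct effect defaults to minus the expected mediated path
#' `(delta_htn * beta_htn + delta_dm * beta_dm + delta_bmi * beta_bmi)` so
#' the unadjusted contrast is zero in expectation by construction.
#'
#' @param seed Generator seed.
#' @param scale Optional factor applied to both group sizes.
#' @return A [generator_config()].
#' @export
config_suppression <- function(seed = 1L, scale = 1) {
  beta_htn <- 0.5
  beta_dm <- 0.5
  beta_bmi <- 0.02
  d_htn <- 0.70 - 0.30
  d_dm <- 0.35 - 0.08
  d_bmi <- 29.5 - 26.5
  mediated <- d_htn * beta_htn + d_dm * beta_dm + d_bmi * beta_bmi
  n <- function(k) max(2L, as.integer(round(k * scale)))
  profiles <- list(
    group_profile("Non-Hispanic", n = n(8307), age_mean = 71.38, age_sd = 9.19,
                  edu_mean = 16.18, edu_sd = 2.73, bmi_mean = 26.5, bmi_sd = 5.0,
                  male_frac = 0.45, htn_prev = 0.30, dm_prev = 0.08,
                  dx_probs = c(4330, 837, 3140) / 8307),
    group_profile("Hispanic", n = n(661), age_mean = 71.47, age_sd = 8.66,
                  edu_mean = 13.61, edu_sd = 4.54, bmi_mean = 29.5, bmi_sd = 5.0,
                  male_frac = 0.37, htn_prev = 0.70, dm_prev = 0.35,
                  dx_probs = c(301, 130, 230) / 661)
  )
  generator_config(
    profiles = profiles,
    outcome = outcome_params(beta_group = c(Hispanic = -mediated),
                             beta_htn = beta_htn, beta_dm = beta_dm,
                             beta_bmi = beta_bmi,
                             slope_time_by_group = c("Non-Hispanic" = 0.08,
                                                     "Hispanic" = 0.06)),
    seed = seed
  )
}

#' Null scenario: two groups with identical distributions and no group effect
#'
#' Both groups share one set of marginals and the outcome model has no group
#' term and no group-specific slope difference, so any detected contrast is
#' spurious. Used for calibration checks of the resampling pipeline.
#'
#' Group sizes default to an 8:1 reference:target ratio, matching the most
#' unfavourable reference-pool ratio among the cohort's real contrasts.
#'
#' @param n_reference,n_target Group sizes.
#' @param seed Generator seed.
#' @return A [generator_config()].
#' @export
config_null <- function(n_reference = 2400, n_target = 300, seed = 1L) {
  mk <- function(label, n) {
    group_profile(label, n = n, age_mean = 71.36, age_sd = 9.23,
                  edu_mean = 16.31, edu_sd = 2.67, bmi_mean = 26.72, bmi_sd = 5.00,
                  male_frac = 0.47, htn_prev = 0.42, dm_prev = 0.09,
                  dx_probs = c(0.54, 0.09, 0.37))
  }
  generator_config(
    profiles = list(mk("RefGroup", n_reference), mk("TargetGroup", n_target)),
    outcome = outcome_params(beta_group = numeric(),
                             slope_time_by_group = c(RefGroup = 0.08, TargetGroup = 0.08)),
    seed = seed
  )
}
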