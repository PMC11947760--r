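# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_field <- function(field, msg) {
  rlang::abort(sprintf("Invalid field `%s`: %s", field, msg), class = "wmhboot_config_error")
}

check_number <- function(x, field, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_field(field, "must be a single finite number")
  }
  if (strict_lower && x <= lower) abort_field(field, sprintf("must be > %s", lower))
  if (!strict_lower && x < lower) abort_field(field, sprintf("must be >= %s", lower))
  if (x > upper) abort_field(field, sprintf("must be <= %s", upper))
  invisible(x)
}

check_prop <- function(x, field) check_number(x, field, lower = 0, upper = 1)

#' Derive a per-iteration seed from a master seed
#'
#' Iteration seeds are a deterministic arithmetic function of
#' `(master_seed, i)` so that any single iteration of a resampling run can be
#' reproduced in isolation without replaying the iterations before it.
#'
#' @param master_seed Integer master seed of the run.
#' @param i Iteration index (1-based). Vectorised.
#' @return Integer vector of seeds in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' iteration_seed(42L, 1:3)
iteration_seed <- function(master_seed, i) {
  check_number(master_seed, "master_seed")
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.double(master_seed)) %% m) + 1
  # two rounds of a Lehmer-style multiplicative step keep seeds well spread
  x <- (s * 48271 + as.double(i) * 69621) %% m
  x <- (x * 16807 + 17) %% m
  as.integer(x %% (m - 1)) + 1L
}

# Quantile rule used everywhere: linear interpolation between order statistics
# (stats::quantile type 7).
pctl <- function(x, probs) unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))

required_cohort_columns <- function() {
  c("id", "group", "ethnicity", "age", "sex", "education", "diagnosis",
    "bmi", "hypertension", "diabetes", "time_from_baseline_days",
    "wmh_severity", "wmh_total_mm3", "wmh_frontal_mm3", "wmh_parietal_mm3",
    "wmh_temporal_mm3", "wmh_occipital_mm3")
}

check_cohort <- function(cohort, need = required_cohort_columns()) {
  if (!is.data.frame(cohort)) {
    rlang::abort("`cohort` must be a data frame", class = "wmhboot_schema_error")
  }
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L) {
    rlang::abort(
      sprintf("cohort is missing required column(s): %s", paste(missing_cols, collapse = ", ")),
      class = "wmhboot_schema_error"
    )
  }
  invisible(cohort)
}

# Baseline = first visit of each participant.
baseline_rows <- function(cohort) {
  dplyr::filter(cohort, .data$time_from_baseline_days == 0)
}
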