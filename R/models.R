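# Design construction and model fitting: baseline OLS, longitudinal
# random-intercept GLS (profiled REML), and the descriptive two-group tests.

wmh_outcomes <- c("severity", "log_total", "log_frontal", "log_parietal",
                  "log_temporal", "log_occipital")

#' Specify one group-contrast model
#'
#' Captures the outcome, the contrast (target vs reference group), the
#' covariate set, and the longitudinal/interaction structure of one model:
#'
#' * base, baseline: `WMH ~ Group + Age + Sex + Education + Diagnosis`
#' * vascular adds `Diabetes + Hypertension + BMI`
#' * `longitudinal = TRUE` adds a participant random intercept `(1|ID)`
#' * `interaction = TRUE` (implies longitudinal) adds `TimeFromBaseline +
#'   Group:TimeFromBaseline`, with age entered at baseline
#'
#' @param outcome One of `"severity"`, `"log_total"`, `"log_frontal"`,
#'   `"log_parietal"`, `"log_temporal"`, `"log_occipital"`. Severity enters
#'   the linear model as numeric 0/1/2; volumes as `log(volume_mm3 + 1)`.
#' @param target_group,reference_group Contrast labels; the reported effect
#'   is target minus reference.
#' @param covariates `"base"` or `"vascular"`.
#' @param longitudinal Add a participant random intercept.
#' @param interaction Add time and group-by-time terms (requires
#'   `longitudinal = TRUE`).
#' @param group_col Column with group labels (`"group"` or `"ethnicity"`).
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("severity", "Black", "White")
#' model_spec("log_total", "Hispanic", "Non-Hispanic",
#'            covariates = "vascular", group_col = "ethnicity")
model_spec <- function(outcome, target_group, reference_group,
                       covariates = c("base", "vascular"),
                       longitudinal = FALSE, interaction = FALSE,
                       group_col = "group") {
  outcome <- match.arg(outcome, wmh_outcomes)
  covariates <- match.arg(covariates)
  if (interaction && !longitudinal) {
    rlang::abort("`interaction = TRUE` requires `longitudinal = TRUE`",
                 class = "wmhboot_config_error")
  }
  stopifnot(is.character(target_group), is.character(reference_group))
  f <- paste0(
    "WMH ~ Group + ", if (interaction) "AgeBaseline" else "Age",
    " + Sex + Education + Diagnosis",
    if (covariates == "vascular") " + Diabetes + Hypertension + BMI" else "",
    if (interaction) " + TimeFromBaseline + Group:TimeFromBaseline" else "",
    if (longitudinal) " + (1|ID)" else ""
  )
  structure(
    list(outcome = outcome, target_group = target_group,
         reference_group = reference_group, covariates = covariates,
         longitudinal = longitudinal, interaction = interaction,
         group_col = group_col, formula = f),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s vs %s on %s\n  %s\n",
              x$target_group, x$reference_group, x$outcome, x$formula))
  invisible(x)
}

outcome_vector <- function(cohort, outcome) {
  if (outcome == "severity") {
    as.numeric(cohort$wmh_severity)
  } else {
    col <- paste0("wmh_", sub("^log_", "", outcome), "_mm3")
    log(cohort[[col]] + 1)
  }
}

#' Build the response, design matrix and id vector for a model
#'
#' Restricts the cohort to the two contrast groups, codes the design
#' (reference-coded group indicator; male = 1; diagnosis dummy-coded against
#' NC; time in years via days/365.25; log volumes as `log(x + 1)`), and
#' drops rows with missing model variables (complete-case analysis, dropped
#' rows counted).
#'
#' @param cohort A participant-visit cohort table.
#' @param spec A [model_spec()].
#' @return A list with `y`, `X`, `id`, `n_dropped`, and the coefficient
#'   names of the group effect (`term_group`) and, when present, the
#'   group-by-time interaction (`term_interaction`).
#' @export
build_design <- function(cohort, spec) {
  stopifnot(inherits(spec, "model_spec"))
  check_cohort(cohort)
  g <- cohort[[spec$group_col]]
  d <- cohort[g %in% c(spec$target_group, spec$reference_group), ]
  if (!spec$longitudinal) d <- baseline_rows(d)
  if (nrow(d) == 0L) {
    rlang::abort("no rows for the requested contrast", class = "wmhboot_design_error")
  }
  if (spec$interaction) {
    # age at the participant's baseline visit
    d <- d |>
      dplyr::group_by(.data$id) |>
      dplyr::mutate(age = .data$age[which.min(.data$time_from_baseline_days)]) |>
      dplyr::ungroup()
  }
  y <- outcome_vector(d, spec$outcome)
  grp <- as.numeric(d[[spec$group_col]] == spec$target_group)
  term_group <- paste0("group", spec$target_group)
  X <- cbind(
    "(Intercept)" = 1,
    stats::setNames(list(grp), term_group)[[1]],
    age = d$age,
    sexmale = as.numeric(d$sex == "male"),
    education = d$education,
    diagnosisMCI = as.numeric(d$diagnosis == "MCI"),
    diagnosisAD = as.numeric(d$diagnosis == "AD")
  )
  colnames(X)[2] <- term_group
  if (spec$covariates == "vascular") {
    X <- cbind(X, diabetes = d$diabetes, hypertension = d$hypertension, bmi = d$bmi)
  }
  term_interaction <- NULL
  if (spec$interaction) {
    t_years <- d$time_from_baseline_days / 365.25
    term_interaction <- paste0(term_group, ":time_years")
    X <- cbind(X, time_years = t_years)
    X <- cbind(X, stats::setNames(list(grp * t_years), term_interaction)[[1]])
    colnames(X)[ncol(X)] <- term_interaction
  }
  ok <- stats::complete.cases(cbind(y, X))
  n_dropped <- sum(!ok)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  id <- d$id[ok]
  if (length(y) == 0L) {
    rlang::abort("no complete cases for the requested model", class = "wmhboot_design_error")
  }
  const <- vapply(seq_len(ncol(X))[-1], function(j) stats::var(X[, j]) == 0, TRUE)
  if (any(const)) {
    rlang::abort(sprintf("constant design column(s) after filtering: %s",
                         paste(colnames(X)[-1][const], collapse = ", ")),
                 class = "wmhboot_design_error")
  }
  list(y = y, X = X, id = id, n_dropped = n_dropped,
       term_group = term_group, term_interaction = term_interaction,
       spec = spec)
}

new_wmh_fit <- function(terms, est, se, df, dof_method, sigma2, n_obs,
                        n_subjects, method, exact_fit = FALSE,
                        var_subject = NA_real_, var_resid = sigma2,
                        boundary = FALSE, lambda = NA_real_,
                        profile = NULL, formula = NULL, n_dropped = 0L) {
  tstat <- est / se
  p <- if (dof_method == "t") {
    2 * stats::pt(-abs(tstat), df)
  } else {
    2 * stats::pnorm(-abs(tstat))
  }
  structure(
    list(
      coefficients = tibble::tibble(term = terms, estimate = est,
                                    std_error = se, t_statistic = tstat,
                                    p_value = p),
      df = df, dof_method = dof_method, sigma2 = sigma2,
      var_subject = var_subject, var_resid = var_resid, lambda = lambda,
      n_obs = n_obs, n_subjects = n_subjects, method = method,
      exact_fit = exact_fit, boundary = boundary, profile = profile,
      formula = formula, n_dropped = n_dropped
    ),
    class = "wmh_fit"
  )
}

#' Fit a linear model by ordinary least squares
#'
#' QR-based least squares with classical standard errors, t-statistics with
#' `n - rank` degrees of freedom and two-sided p-values. An (near-)exact fit
#' (residual sum of squares numerically zero) is flagged via `exact_fit`
#' rather than reported as spuriously precise inference.
#'
#' @param y Response vector.
#' @param X Design matrix including the intercept column.
#' @param ... Unused.
#' @return An object of class `wmh_fit`; see [tidy.wmh_fit()].
#' @export
fit_ols <- function(y, X, ...) {
  stopifnot(is.numeric(y), is.matrix(X), nrow(X) == length(y))
  qx <- qr(X)
  p <- ncol(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    rlang::abort(sprintf("design matrix is rank deficient; collinear column(s): %s",
                         paste(bad, collapse = ", ")),
                 class = "wmhboot_fit_error")
  }
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  df <- length(y) - qx$rank
  if (df <= 0L) {
    rlang::abort("no residual degrees of freedom", class = "wmhboot_fit_error")
  }
  exact <- rss < 1e-10 * max(1, sum(y^2))
  sigma2 <- rss / df
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(pmax(sigma2 * diag(xtx_inv), 0))
  new_wmh_fit(colnames(X), as.numeric(beta), se, df, "t", sigma2,
              n_obs = length(y), n_subjects = length(y), method = "ols",
              exact_fit = exact)
}

#' Fit a linear model with a participant random intercept by REML
#'
#' Restricted maximum likelihood for the model `y = X b + Z u + e`, `u ~
#' N(0, sigma_subject^2)` per participant, by profiling the single variance
#' ratio `lambda = sigma_subject^2 / sigma_resid^2`: for fixed lambda the
#' fixed effects are generalised least squares and both variances have
#' closed forms, leaving a one-dimensional REML criterion minimised over
#' `log(lambda)`. Fixed-effect standard errors come from the GLS information
#' matrix; p-values use the normal approximation. A boundary estimate
#' (subject variance ~ 0) is allowed and flagged.
#'
#' @param y Response vector.
#' @param X Design matrix including the intercept column.
#' @param ids Participant identifier per row.
#' @param lambda_range Search range for `log(lambda)`.
#' @return An object of class `wmh_fit` with variance components
#'   `var_subject` and `var_resid` and the REML profile trace in `$profile`.
#' @export
fit_random_intercept <- function(y, X, ids, lambda_range = c(-14, 10)) {
  stopifnot(is.numeric(y), is.matrix(X), nrow(X) == length(y),
            length(ids) == length(y))
  if (length(unique(ids)) < 2L) {
    rlang::abort("need at least 2 participants", class = "wmhboot_fit_error")
  }
  p <- ncol(X)
  n <- length(y)
  if (qr(X)$rank < p) {
    rlang::abort("design matrix is rank deficient", class = "wmhboot_fit_error")
  }
  f <- factor(ids)
  S <- rowsum(X, f)                       # per-subject column sums of X
  sy <- as.numeric(rowsum(y, f))
  ni <- as.numeric(rowsum(rep(1, n), f))
  XtX <- crossprod(X)
  Xty <- as.numeric(crossprod(X, y))
  yty <- sum(y^2)

  gls_parts <- function(lambda) {
    w <- lambda / (1 + ni * lambda)
    A <- XtX - crossprod(S, S * w)
    b <- Xty - as.numeric(crossprod(S, sy * w))
    q <- yty - sum(w * sy^2)
    beta <- solve(A, b)
    rss <- max(q - sum(b * beta), 1e-300)
    list(A = A, beta = beta, rss = rss, w = w)
  }
  crit <- function(lambda) {
    gp <- gls_parts(lambda)
    ld_A <- as.numeric(determinant(gp$A, logarithm = TRUE)$modulus)
    sum(log1p(ni * lambda)) + ld_A + (n - p) * log(gp$rss)
  }
  trace_env <- new.env()
  trace_env$rows <- list()
  crit_traced <- function(theta) {
    v <- crit(exp(theta))
    trace_env$rows[[length(trace_env$rows) + 1L]] <-
      c(log_lambda = theta, criterion = v)
    v
  }
  opt <- stats::optimize(crit_traced, interval = lambda_range, tol = 1e-9)
  lambda <- exp(opt$minimum)
  c0 <- crit(0)
  boundary <- c0 <= opt$objective + 1e-8 || opt$minimum <= lambda_range[1] + 1e-6
  if (boundary && c0 <= opt$objective + 1e-8) lambda <- 0

  gp <- gls_parts(lambda)
  sigma2 <- gp$rss / (n - p)
  cov_beta <- sigma2 * solve(gp$A)
  se <- unname(sqrt(pmax(diag(cov_beta), 0)))
  profile <- do.call(rbind, trace_env$rows)
  new_wmh_fit(colnames(X), as.numeric(gp$beta), se, df = n - p,
              dof_method = "normal", sigma2 = sigma2, n_obs = n,
              n_subjects = nlevels(f), method = "reml_random_intercept",
              var_subject = lambda * sigma2, var_resid = sigma2,
              boundary = boundary, lambda = lambda,
              profile = tibble::as_tibble(profile))
}

#' Fit a model specification to a cohort
#'
#' Builds the design via [build_design()] and dispatches to [fit_ols()]
#' (baseline) or [fit_random_intercept()] (longitudinal).
#'
#' @param cohort A participant-visit cohort table.
#' @param spec A [model_spec()].
#' @return A `wmh_fit` object.
#' @export
#' @examples
#' cfg <- generator_config(clinical_cohort_profiles(scale = 0.05), seed = 2)
#' cohort <- cohort_baseline(cfg)
#' fit <- fit_wmh_model(cohort, model_spec("log_total", "Black", "White"))
#' tidy(fit)
fit_wmh_model <- function(cohort, spec) {
  dd <- build_design(cohort, spec)
  fit <- if (spec$longitudinal) {
    fit_random_intercept(dd$y, dd$X, dd$id)
  } else {
    fit_ols(dd$y, dd$X)
  }
  fit$formula <- spec$formula
  fit$n_dropped <- dd$n_dropped
  fit$term_group <- dd$term_group
  fit$term_interaction <- dd$term_interaction
  fit
}

#' @export
print.wmh_fit <- function(x, ...) {
  cat(sprintf("<wmh_fit> %s, n_obs = %d, n_subjects = %d\n",
              x$method, x$n_obs, x$n_subjects))
  if (!is.null(x$formula)) cat(" ", x$formula, "\n")
  print(x$coefficients)
  if (x$method == "reml_random_intercept") {
    cat(sprintf("  var_subject = %.4g, var_resid = %.4g%s\n",
                x$var_subject, x$var_resid,
                if (x$boundary) " (boundary: subject variance ~ 0)" else ""))
  }
  invisible(x)
}

#' Tidy a model fit into a coefficient tibble
#'
#' @param x A `wmh_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std_error`,
#'   `t_statistic`, `p_value`.
#' @method tidy wmh_fit
#' @export
tidy.wmh_fit <- function(x, ...) x$coefficients

#' One-row model-level summary of a fit
#'
#' @param x A `wmh_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with sample sizes, residual/subject variances,
#'   degrees-of-freedom convention and flags.
#' @method glance wmh_fit
#' @export
glance.wmh_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_obs = x$n_obs, n_subjects = x$n_subjects,
    df = x$df, dof_method = x$dof_method,
    var_subject = x$var_subject, var_resid = x$var_resid,
    exact_fit = x$exact_fit, boundary = x$boundary,
    n_dropped = x$n_dropped
  )
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance (Welch) t statistic with Welch-Satterthwaite degrees of
#' freedom and two-sided p-value, computed from group means, SDs and sizes
#' (as reported in descriptive cohort tables).
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A one-row tibble with `t_statistic`, `dof`, `p_value`.
#' @export
#' @examples
#' welch_t(16.31, 2.67, 7132, 15.08, 2.81, 892) # education, two groups
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  check_number(mean1, "mean1"); check_number(mean2, "mean2")
  check_number(sd1, "sd1", lower = 0, strict_lower = TRUE)
  check_number(sd2, "sd2", lower = 0, strict_lower = TRUE)
  check_number(n1, "n1", lower = 2)
  check_number(n2, "n2", lower = 2)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  dof <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(t_statistic = t, dof = dof,
                 p_value = 2 * stats::pt(-abs(t), dof))
}

#' Pearson chi-square test for a 2 x k contingency table
#'
#' Pearson statistic without continuity correction, `(r-1)(k-1)` degrees of
#' freedom.
#'
#' @param counts A 2 x k matrix of counts.
#' @return A one-row tibble with `chi2`, `dof`, `p_value`.
#' @export
#' @examples
#' chi_square(matrix(c(3364, 244, 3768, 648), nrow = 2)) # sex by group
chi_square <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts) || nrow(counts) != 2L) {
    rlang::abort("`counts` must be a numeric 2 x k matrix", class = "wmhboot_config_error")
  }
  if (any(counts < 0)) {
    rlang::abort("counts must be non-negative", class = "wmhboot_config_error")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    rlang::abort("zero marginal in contingency table", class = "wmhboot_config_error")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(chi2 = unname(ct$statistic), dof = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}

#' Harmonise raw multi-source vascular columns into analysis columns
#'
#' Merges the overlapping raw indicator columns used across cohort freezes
#' (`HYPERT`/`HXHYPER`/`HYPERTEN` for hypertension, `DIABET`/`DIABETES` for
#' diabetes) with an any-positive rule: 1 if any available source indicates
#' presence, 0 if at least one source is observed and none indicates
#' presence, missing if all sources are missing. BMI is taken from `NACCBMI`
#' (or an existing `bmi` column) with a 12-70 kg/m2 plausibility range check
#' (values outside become missing).
#'
#' @param raw A data frame with at least one source column per factor.
#' @return `raw` with harmonised `hypertension`, `diabetes` and `bmi`
#'   columns (source columns removed).
#' @export
harmonize_vascular_columns <- function(raw) {
  stopifnot(is.data.frame(raw))
  merge_any <- function(cols, what) {
    present <- intersect(cols, names(raw))
    if (length(present) == 0L) {
      rlang::abort(sprintf("no source column for %s (looked for %s)",
                           what, paste(cols, collapse = ", ")),
                   class = "wmhboot_schema_error")
    }
    m <- as.matrix(raw[present])
    storage.mode(m) <- "double"
    pos <- rowSums(m > 0, na.rm = TRUE) > 0
    seen <- rowSums(!is.na(m)) > 0
    out <- ifelse(pos, 1L, ifelse(seen, 0L, NA_integer_))
    list(value = out, drop = present)
  }
  htn <- merge_any(c("HYPERT", "HXHYPER", "HYPERTEN"), "hypertension")
  dm <- merge_any(c("DIABET", "DIABETES"), "diabetes")
  bmi_src <- intersect(c("NACCBMI", "bmi"), names(raw))
  if (length(bmi_src) == 0L) {
    rlang::abort("no source column for bmi (looked for NACCBMI, bmi)",
                 class = "wmhboot_schema_error")
  }
  bmi <- as.numeric(raw[[bmi_src[1]]])
  bmi[!is.na(bmi) & (bmi < 12 | bmi > 70)] <- NA_real_
  out <- raw[setdiff(names(raw), c(htn$drop, dm$drop, "NACCBMI"))]
  out$hypertension <- htn$value
  out$diabetes <- dm$value
  out$bmi <- bmi
  tibble::as_tibble(out)
}
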