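# The matched-bootstrap engine: repeat covariate-matched subsampling of the
# reference group, fit the contrast model on each balanced sample, and
# aggregate the per-iteration group effects and t-statistics into medians
# and percentile confidence intervals at the 95% and 99.5% levels.

#' Aggregate per-iteration statistics into a resampling summary
#'
#' Medians of the per-iteration effect sizes, t-statistics and p-values, and
#' percentile confidence intervals of the t-statistic formed from
#' linear-interpolation empirical quantiles at `(1 - level)/2` and
#' `(1 + level)/2`. An interval "excludes zero" when both bounds share a
#' strict sign.
#'
#' @param effects,tstats,pvals Equal-length numeric vectors, one value per
#'   successful iteration.
#' @param levels Confidence levels for the t-statistic intervals.
#' @return A list with `median_effect`, `median_t`, `median_p`, `ci95_t`,
#'   `ci995_t`, `excludes_zero_95`, `excludes_zero_995`.
#' @export
#' @examples
#' aggregate_iterations(rnorm(100), rnorm(100, 3), runif(100, 0, 0.1))
aggregate_iterations <- function(effects, tstats, pvals,
                                 levels = c(0.95, 0.995)) {
  n <- length(tstats)
  if (n == 0L) {
    rlang::abort("no successful iterations to aggregate", class = "wmhboot_resample_error")
  }
  if (length(effects) != n || length(pvals) != n) {
    rlang::abort("`effects`, `tstats` and `pvals` must have equal length",
                 class = "wmhboot_resample_error")
  }
  ci <- function(level) pctl(tstats, c((1 - level) / 2, (1 + level) / 2))
  excl <- function(bounds) bounds[1] > 0 || bounds[2] < 0
  ci95 <- ci(levels[1])
  ci995 <- ci(levels[2])
  list(median_effect = stats::median(effects),
       median_t = stats::median(tstats),
       median_p = stats::median(pvals),
       ci95_t = ci95, ci995_t = ci995,
       excludes_zero_95 = excl(ci95), excludes_zero_995 = excl(ci995))
}

specs_share_contrast <- function(specs) {
  ref <- specs[[1]]
  same <- vapply(specs, function(sp) {
    identical(sp$target_group, ref$target_group) &&
      identical(sp$reference_group, ref$reference_group) &&
      identical(sp$group_col, ref$group_col)
  }, TRUE)
  if (!all(same)) {
    rlang::abort("all model specs must share the same contrast",
                 class = "wmhboot_config_error")
  }
}

# Shared engine: one set of match plans per iteration, any number of model
# specs fitted on each plan. Returns one resample_summary per spec.
resample_engine <- function(cohort, specs, n_iterations, master_seed,
                            k_nearest = 10L, replace_infeasible = FALSE,
                            max_fail_frac = 0.05) {
  check_number(n_iterations, "n_iterations", lower = 1)
  check_number(master_seed, "master_seed")
  stopifnot(length(specs) >= 1)
  specs_share_contrast(specs)
  sp1 <- specs[[1]]
  ctx <- match_context(cohort, sp1$reference_group, sp1$target_group, sp1$group_col)

  prep <- lapply(specs, function(sp) {
    dd <- build_design(cohort, sp)
    dd$rows_by_id <- split(seq_along(dd$id), dd$id)
    dd$i_group <- match(dd$term_group, colnames(dd$X))
    dd$i_int <- if (is.null(dd$term_interaction)) NA_integer_ else
      match(dd$term_interaction, colnames(dd$X))
    dd
  })

  seeds <- iteration_seed(master_seed, seq_len(n_iterations))
  n_spec <- length(specs)
  trace <- lapply(seq_len(n_spec), function(s) {
    tibble::tibble(iteration = seq_len(n_iterations), seed = seeds,
                   effect = NA_real_, se = NA_real_, t = NA_real_,
                   p = NA_real_, effect_interaction = NA_real_,
                   t_interaction = NA_real_, p_interaction = NA_real_,
                   ok = FALSE, error = NA_character_)
  })

  for (i in seq_len(n_iterations)) {
    sel <- tryCatch(match_select(ctx, seeds[i], k_nearest, replace_infeasible),
                    error = function(e) e)
    if (inherits(sel, "error")) {
      for (s in seq_len(n_spec)) trace[[s]]$error[i] <- conditionMessage(sel)
      next
    }
    ids <- c(ctx$tgt$id, ctx$ref$id[sel$selected])
    for (s in seq_len(n_spec)) {
      pp <- prep[[s]]
      rows <- unlist(pp$rows_by_id[ids], use.names = FALSE)
      fit <- tryCatch({
        if (specs[[s]]$longitudinal) {
          fit_random_intercept(pp$y[rows], pp$X[rows, , drop = FALSE], pp$id[rows])
        } else {
          fit_ols(pp$y[rows], pp$X[rows, , drop = FALSE])
        }
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        trace[[s]]$error[i] <- conditionMessage(fit)
        next
      }
      co <- fit$coefficients
      trace[[s]]$effect[i] <- co$estimate[pp$i_group]
      trace[[s]]$se[i] <- co$std_error[pp$i_group]
      trace[[s]]$t[i] <- co$t_statistic[pp$i_group]
      trace[[s]]$p[i] <- co$p_value[pp$i_group]
      if (!is.na(pp$i_int)) {
        trace[[s]]$effect_interaction[i] <- co$estimate[pp$i_int]
        trace[[s]]$t_interaction[i] <- co$t_statistic[pp$i_int]
        trace[[s]]$p_interaction[i] <- co$p_value[pp$i_int]
      }
      trace[[s]]$ok[i] <- TRUE
    }
  }

  out <- lapply(seq_len(n_spec), function(s) {
    tr <- trace[[s]]
    n_failed <- sum(!tr$ok)
    if (n_failed > max_fail_frac * n_iterations) {
      rlang::abort(sprintf(
        "%d of %d iterations failed (> %.0f%%); first error: %s",
        n_failed, n_iterations, 100 * max_fail_frac,
        tr$error[!tr$ok][1]), class = "wmhboot_resample_error")
    }
    ok <- tr$ok
    agg <- aggregate_iterations(tr$effect[ok], tr$t[ok], tr$p[ok])
    sp <- specs[[s]]
    res <- c(
      list(model_id = model_id(sp), spec = sp,
           contrast = paste(sp$target_group, "vs", sp$reference_group),
           n_iterations = n_iterations, n_failed = n_failed,
           master_seed = as.integer(master_seed), trace = tr),
      agg
    )
    if (sp$interaction) {
      res$interaction <- aggregate_iterations(tr$effect_interaction[ok],
                                              tr$t_interaction[ok],
                                              tr$p_interaction[ok])
    }
    structure(res, class = "resample_summary")
  })
  names(out) <- vapply(specs, model_id, "")
  out
}

model_id <- function(sp) {
  kind <- if (sp$interaction) "progression" else if (sp$longitudinal) "longitudinal" else "baseline"
  paste(sp$outcome, kind, sp$covariates, sep = "_")
}

#' Run a matched-bootstrap group contrast
#'
#' The headline procedure: for each of `n_iterations` iterations (seeded
#' deterministically from `master_seed` via [iteration_seed()]), build a
#' covariate-matched subsample of the reference group ([match_subsample()]),
#' expand to all visits when the model is longitudinal, fit the specified
#' model, and record the group effect and its t-statistic. Iterations whose
#' fit fails are excluded and counted; more than 5% failures aborts the run.
#'
#' @param cohort A participant-visit cohort table.
#' @param spec A [model_spec()].
#' @param n_iterations Number of matched resampling iterations (default
#'   1000).
#' @param master_seed Master seed of the run.
#' @param k_nearest,replace_infeasible Passed to the matcher; see
#'   [match_subsample()].
#' @return An object of class `resample_summary`: medians and percentile CIs
#'   (see [aggregate_iterations()]), exclusion flags, failure count, and the
#'   full per-iteration trace in `$trace`. For interaction models the
#'   group-by-time coefficient is aggregated separately in `$interaction`.
#' @export
#' @examples
#' cfg <- generator_config(clinical_cohort_profiles(scale = 0.05), seed = 3)
#' cohort <- cohort_baseline(cfg)
#' resample_contrast(cohort, model_spec("log_total", "Black", "White"),
#'                   n_iterations = 20, master_seed = 1)
resample_contrast <- function(cohort, spec, n_iterations = 1000,
                              master_seed = 1L, k_nearest = 10L,
                              replace_infeasible = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  resample_engine(cohort, list(spec), n_iterations, master_seed,
                  k_nearest, replace_infeasible)[[1]]
}

#' @export
print.resample_summary <- function(x, ...) {
  cat(sprintf("<resample_summary> %s | %s\n", x$model_id, x$contrast))
  cat(sprintf("  iterations: %d (%d failed), master seed %d\n",
              x$n_iterations, x$n_failed, x$master_seed))
  cat(sprintf("  median effect %.3f, median t %.2f (median p %.3g)\n",
              x$median_effect, x$median_t, x$median_p))
  cat(sprintf("  95%% CI of t: (%.2f, %.2f)%s   99.5%% CI: (%.2f, %.2f)%s\n",
              x$ci95_t[1], x$ci95_t[2], if (x$excludes_zero_95) " *" else "",
              x$ci995_t[1], x$ci995_t[2], if (x$excludes_zero_995) " *" else ""))
  invisible(x)
}

#' Tidy a resampling summary into one row
#'
#' @param x A `resample_summary` object.
#' @param ... Unused.
#' @return A one-row tibble (two rows for interaction models: the group main
#'   effect and the group-by-time term).
#' @method tidy resample_summary
#' @export
tidy.resample_summary <- function(x, ...) {
  row <- function(term, a) {
    tibble::tibble(
      model = x$model_id, contrast = x$contrast, term = term,
      median_effect = a$median_effect, median_t = a$median_t,
      median_p = a$median_p,
      ci995_lower = a$ci995_t[1], ci995_upper = a$ci995_t[2],
      ci95_lower = a$ci95_t[1], ci95_upper = a$ci95_t[2],
      excludes_zero_95 = a$excludes_zero_95,
      excludes_zero_995 = a$excludes_zero_995,
      n_iterations = x$n_iterations, n_failed = x$n_failed
    )
  }
  out <- row("group", x)
  if (!is.null(x$interaction)) {
    out <- dplyr::bind_rows(out, row("group:time", x$interaction))
  }
  out
}

#' Compare base against vascular-adjusted covariate sets on shared plans
#'
#' Runs the same contrast twice -- once with the base covariate set, once
#' adding diabetes, hypertension and BMI -- reusing identical match plans in
#' each iteration (same derived seeds), so the adjustment effect is not
#' confounded by resampling noise. The comparison is classified by the 95%
#' exclusion flags: `"attenuated"` when a significant unadjusted contrast
#' loses significance after adjustment, `"revealed"` when a null unadjusted
#' contrast becomes significant (suppression), `"unchanged"` otherwise.
#'
#' @param cohort A participant-visit cohort table.
#' @param spec A [model_spec()] with the base covariate set.
#' @inheritParams resample_contrast
#' @return An object of class `wmh_adjustment_comparison` with elements
#'   `unadjusted`, `adjusted` (both `resample_summary`), `delta_median_t`,
#'   `delta_median_effect`, `classification`.
#' @export
compare_adjustment <- function(cohort, spec, n_iterations = 1000,
                               master_seed = 1L, k_nearest = 10L,
                               replace_infeasible = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$covariates != "base") {
    rlang::abort("`spec` must use the base covariate set", class = "wmhboot_config_error")
  }
  spec_v <- model_spec(spec$outcome, spec$target_group, spec$reference_group,
                       covariates = "vascular", longitudinal = spec$longitudinal,
                       interaction = spec$interaction, group_col = spec$group_col)
  fits <- resample_engine(cohort, list(spec, spec_v), n_iterations,
                          master_seed, k_nearest, replace_infeasible)
  un <- fits[[1]]
  ad <- fits[[2]]
  classification <- if (un$excludes_zero_95 && !ad$excludes_zero_95) {
    "attenuated"
  } else if (!un$excludes_zero_95 && ad$excludes_zero_95) {
    "revealed"
  } else {
    "unchanged"
  }
  structure(
    list(unadjusted = un, adjusted = ad,
         delta_median_t = ad$median_t - un$median_t,
         delta_median_effect = ad$median_effect - un$median_effect,
         classification = classification),
    class = "wmh_adjustment_comparison"
  )
}

#' @export
print.wmh_adjustment_comparison <- function(x, ...) {
  cat(sprintf("<wmh_adjustment_comparison> %s: %s\n",
              x$unadjusted$contrast, x$classification))
  cat(sprintf("  median t %.2f -> %.2f (delta %.2f); median effect %.3f -> %.3f\n",
              x$unadjusted$median_t, x$adjusted$median_t, x$delta_median_t,
              x$unadjusted$median_effect, x$adjusted$median_effect))
  invisible(x)
}

#' @method tidy wmh_adjustment_comparison
#' @export
tidy.wmh_adjustment_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$unadjusted), adjustment = "base", .before = 1),
    dplyr::mutate(tidy(x$adjusted), adjustment = "vascular", .before = 1)
  )
}

#' @method glance wmh_adjustment_comparison
#' @export
glance.wmh_adjustment_comparison <- function(x, ...) {
  tibble::tibble(contrast = x$unadjusted$contrast,
                 model = x$unadjusted$model_id,
                 delta_median_t = x$delta_median_t,
                 delta_median_effect = x$delta_median_effect,
                 classification = x$classification)
}

#' Baseline contrast panel over total and regional volumes
#'
#' Runs the baseline model for the total volume and each regional volume
#' (frontal, parietal, temporal, occipital), each with both the base and the
#' vascular covariate set (10 summaries), reusing identical match plans
#' across all outcomes within an iteration.
#'
#' @param cohort A participant-visit cohort table with volumetric outcomes.
#' @param target_group,reference_group Contrast labels.
#' @param n_iterations,master_seed,k_nearest,replace_infeasible See
#'   [resample_contrast()].
#' @param group_col Column with group labels.
#' @return An object of class `wmh_panel`: a named list of
#'   `resample_summary` objects.
#' @export
regional_panel <- function(cohort, target_group, reference_group,
                           n_iterations = 1000, master_seed = 1L,
                           group_col = "group", k_nearest = 10L,
                           replace_infeasible = FALSE) {
  outcomes <- c("log_total", "log_frontal", "log_parietal", "log_temporal",
                "log_occipital")
  specs <- list()
  for (o in outcomes) {
    for (cv in c("base", "vascular")) {
      specs[[length(specs) + 1L]] <-
        model_spec(o, target_group, reference_group, covariates = cv,
                   group_col = group_col)
    }
  }
  out <- resample_engine(cohort, specs, n_iterations, master_seed,
                         k_nearest, replace_infeasible)
  structure(out, class = c("wmh_panel", "list"))
}

#' @method tidy wmh_panel
#' @export
tidy.wmh_panel <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), tidy))
}

#' @export
print.wmh_panel <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}
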