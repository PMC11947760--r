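# Cohort file IO, study orchestration, and table rendering.

#' Read a cohort table from delimited text
#'
#' Reads a comma-separated participant-visit table (header row, UTF-8,
#' empty fields as missing), validates the schema and categorical levels,
#' and harmonises raw multi-source vascular columns
#' (`HYPERT`/`HXHYPER`/`HYPERTEN`, `DIABET`/`DIABETES`, `NACCBMI`) via
#' [harmonize_vascular_columns()] when they are present instead of the
#' analysis columns.
#'
#' @param path Path to a CSV file.
#' @param quiet Suppress the row/participant count message.
#' @return A validated participant-visit tibble.
#' @export
read_cohort <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("cohort file not found: %s", path), class = "wmhboot_io_error")
  }
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       na = c("", "NA"))
  raw_vascular <- c("HYPERT", "HXHYPER", "HYPERTEN", "DIABET", "DIABETES", "NACCBMI")
  if (any(raw_vascular %in% names(d)) &&
      !all(c("hypertension", "diabetes", "bmi") %in% names(d))) {
    d <- harmonize_vascular_columns(d)
  }
  check_cohort(d)
  bad_sex <- which(!d$sex %in% c("male", "female") & !is.na(d$sex))
  if (length(bad_sex) > 0L) {
    rlang::abort(sprintf("invalid sex values (expected male/female) at row(s): %s",
                         paste(utils::head(bad_sex, 5), collapse = ", ")),
                 class = "wmhboot_schema_error")
  }
  bad_dx <- which(!d$diagnosis %in% c("NC", "MCI", "AD") & !is.na(d$diagnosis))
  if (length(bad_dx) > 0L) {
    rlang::abort(sprintf("invalid diagnosis values (expected NC/MCI/AD) at row(s): %s",
                         paste(utils::head(bad_dx, 5), collapse = ", ")),
                 class = "wmhboot_schema_error")
  }
  if (!quiet) {
    message(sprintf("read %d rows, %d participants, groups: %s",
                    nrow(d), dplyr::n_distinct(d$id),
                    paste(sort(unique(d$group)), collapse = ", ")))
  }
  d
}

#' Write a cohort table as delimited text
#'
#' Comma-separated, header row, UTF-8, missing values as empty fields.
#'
#' @param cohort A participant-visit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

model_catalog <- function() {
  tibble::tibble(
    model = 1:6,
    covariates = c("base", "base", "vascular", "vascular", "base", "vascular"),
    longitudinal = c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE),
    interaction = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
}

#' Configure a full study run
#'
#' @param generator A [generator_config()] for synthetic mode, or `NULL`
#'   when reading a cohort from `cohort_path`.
#' @param cohort_path Path to a cohort CSV (ignored in synthetic mode).
#' @param contrasts List of contrasts, each a list with `target`,
#'   `reference` and optionally `group_col` (default `"group"`) and
#'   `outcome` (default `"severity"`).
#' @param models Integer vector of model numbers to run: 1 baseline, 2
#'   longitudinal, 3 baseline + vascular, 4 longitudinal + vascular, 5
#'   progression (group-by-time), 6 progression + vascular.
#' @param n_iterations Matched-resampling iterations per model.
#' @param ci_levels Confidence levels for the t-statistic intervals.
#' @param master_seed Master seed of the whole run.
#' @param output_dir Output directory (created if absent).
#' @param regional Also run the baseline total/regional volume panel.
#' @param quiet Suppress progress messages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       cohort_path = NULL,
                       contrasts = list(list(target = "Black", reference = "White")),
                       models = c(1L, 3L),
                       n_iterations = 1000,
                       ci_levels = c(0.95, 0.995),
                       master_seed = 1L,
                       output_dir = "wmhboot-run",
                       regional = FALSE,
                       quiet = FALSE) {
  if (is.null(generator) && is.null(cohort_path)) {
    abort_field("generator", "either a generator config or a cohort path is required")
  }
  if (!all(models %in% 1:6) || length(models) == 0L) {
    abort_field("models", "must be a non-empty subset of 1:6")
  }
  if (!is.numeric(ci_levels) || any(ci_levels <= 0) || any(ci_levels >= 1)) {
    abort_field("ci_levels", "must lie strictly in (0, 1)")
  }
  if (length(contrasts) == 0L) abort_field("contrasts", "at least one contrast is required")
  contrasts <- lapply(contrasts, function(ct) {
    if (is.null(ct$target) || is.null(ct$reference)) {
      abort_field("contrasts", "each contrast needs `target` and `reference`")
    }
    ct$group_col <- ct$group_col %||% "group"
    ct$outcome <- ct$outcome %||% "severity"
    ct
  })
  check_number(n_iterations, "n_iterations", lower = 1)
  check_number(master_seed, "master_seed")
  structure(
    list(generator = generator, cohort_path = cohort_path,
         contrasts = contrasts, models = as.integer(models),
         n_iterations = n_iterations, ci_levels = ci_levels,
         master_seed = as.integer(master_seed), output_dir = output_dir,
         regional = regional, quiet = quiet),
    class = "run_config"
  )
}

#' Run the full matched-bootstrap study and write its outputs
#'
#' Executes the whole pipeline for a configuration: obtain the cohort
#' (synthetic or from file), produce descriptive group comparisons (Welch t
#' and chi-square tests), run every requested model for every contrast with
#' shared match plans per iteration, optionally run the regional volume
#' panel, and write all tables, per-iteration traces and a run manifest to
#' the output directory.
#'
#' Files written: `descriptives.csv`, `descriptive_tests.csv`,
#' `summary_models.csv` (full precision), `summary_rendered.csv` (2-decimal
#' table layout), `trace_<contrast>_<model>.csv`, optionally
#' `summary_regional.csv`, and `manifest.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the output directory, the tidy summary
#'   table and the summaries themselves.
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$output_dir)) {
    rlang::abort(sprintf("cannot create output directory: %s", config$output_dir),
                 class = "wmhboot_io_error")
  }
  probe <- file.path(config$output_dir, ".write-probe")
  ok <- tryCatch({ writeLines("", probe); TRUE }, error = function(e) FALSE,
                 warning = function(e) FALSE)
  if (!ok) {
    rlang::abort(sprintf("output directory not writable: %s", config$output_dir),
                 class = "wmhboot_io_error")
  }
  unlink(probe)
  say <- function(...) if (!config$quiet) message(sprintf(...))

  cohort <- if (!is.null(config$cohort_path)) {
    say("reading cohort from %s", config$cohort_path)
    read_cohort(config$cohort_path, quiet = config$quiet)
  } else {
    say("generating synthetic cohort (seed %d)", config$generator$seed)
    need_visits <- any(model_catalog()$longitudinal[config$models])
    if (need_visits) cohort_generate(config$generator) else
      cohort_baseline(config$generator)
  }

  out <- function(f) file.path(config$output_dir, f)
  desc_by <- unique(vapply(config$contrasts, `[[`, "", "group_col"))
  descriptives <- dplyr::bind_rows(lapply(desc_by, function(b) {
    dplyr::mutate(summarize_cohort(cohort, by = b), grouping = b, .before = 1)
  }))
  readr::write_csv(descriptives, out("descriptives.csv"), na = "")

  desc_tests <- dplyr::bind_rows(lapply(config$contrasts, function(ct) {
    descriptive_tests(cohort, ct$target, ct$reference, ct$group_col)
  }))
  readr::write_csv(desc_tests, out("descriptive_tests.csv"), na = "")

  cat_tbl <- model_catalog()
  summaries <- list()
  for (ct in config$contrasts) {
    label <- paste(ct$target, "vs", ct$reference)
    say("contrast %s: models %s, %d iterations", label,
        paste(config$models, collapse = ","), config$n_iterations)
    specs <- lapply(config$models, function(m) {
      row <- cat_tbl[cat_tbl$model == m, ]
      model_spec(ct$outcome, ct$target, ct$reference,
                 covariates = row$covariates, longitudinal = row$longitudinal,
                 interaction = row$interaction, group_col = ct$group_col)
    })
    fits <- resample_engine(cohort, specs, config$n_iterations,
                            config$master_seed)
    for (k in seq_along(fits)) {
      s <- fits[[k]]
      s$model_number <- config$models[k]
      summaries[[paste(label, s$model_id)]] <- s
      tr_file <- out(sprintf("trace_%s_model%d.csv",
                             gsub("[^A-Za-z0-9]+", "-", label), config$models[k]))
      readr::write_csv(s$trace, tr_file, na = "")
    }
  }

  tidy_all <- dplyr::bind_rows(lapply(summaries, function(s) {
    dplyr::mutate(tidy(s), model_number = s$model_number, .before = 1)
  }))
  readr::write_csv(tidy_all, out("summary_models.csv"), na = "")
  rendered <- render_summary_table(summaries)
  readr::write_csv(rendered, out("summary_rendered.csv"), na = "")

  regional <- NULL
  if (config$regional) {
    regional <- list()
    for (ct in config$contrasts) {
      label <- paste(ct$target, "vs", ct$reference)
      say("regional panel for %s", label)
      panel <- regional_panel(cohort, ct$target, ct$reference,
                              n_iterations = config$n_iterations,
                              master_seed = config$master_seed,
                              group_col = ct$group_col)
      regional[[label]] <- panel
    }
    reg_tidy <- dplyr::bind_rows(lapply(regional, tidy))
    readr::write_csv(reg_tidy, out("summary_regional.csv"), na = "")
  }

  manifest <- list(
    package = "wmhboot",
    package_version = as.character(utils::packageVersion("wmhboot")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    master_seed = config$master_seed,
    n_iterations = config$n_iterations,
    models = config$models,
    contrasts = lapply(config$contrasts, function(ct) {
      list(target = ct$target, reference = ct$reference,
           group_col = ct$group_col, outcome = ct$outcome)
    }),
    input_mode = if (is.null(config$cohort_path)) "synthetic" else "file",
    generator_seed = if (!is.null(config$generator)) config$generator$seed else NULL
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("outputs written to %s", config$output_dir)
  invisible(list(output_dir = config$output_dir, summary = tidy_all,
                 summaries = summaries, regional = regional,
                 descriptives = descriptives, descriptive_tests = desc_tests))
}

#' Descriptive two-group comparisons (Welch t and chi-square)
#'
#' Welch t-tests for age, education and BMI and chi-square tests for sex,
#' hypertension and diabetes between two groups, from baseline rows.
#'
#' @param cohort A participant-visit cohort table.
#' @param target_group,reference_group Group labels (statistics are target
#'   minus reference for the t-tests).
#' @param group_col Column with the group labels.
#' @return A tibble with one row per variable.
#' @export
descriptive_tests <- function(cohort, target_group, reference_group,
                              group_col = "group") {
  check_cohort(cohort)
  base <- baseline_rows(cohort)
  g <- base[[group_col]]
  a <- base[g == target_group, ]
  b <- base[g == reference_group, ]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    rlang::abort("contrast group absent from cohort", class = "wmhboot_schema_error")
  }
  cont <- dplyr::bind_rows(lapply(c("age", "education", "bmi"), function(v) {
    w <- welch_t(mean(a[[v]], na.rm = TRUE), stats::sd(a[[v]], na.rm = TRUE),
                 sum(!is.na(a[[v]])),
                 mean(b[[v]], na.rm = TRUE), stats::sd(b[[v]], na.rm = TRUE),
                 sum(!is.na(b[[v]])))
    tibble::tibble(variable = v, test = "welch_t", statistic = w$t_statistic,
                   dof = w$dof, p_value = w$p_value)
  }))
  cat_ <- dplyr::bind_rows(lapply(
    list(c("sex", "male"), c("hypertension", "1"), c("diabetes", "1")),
    function(vl) {
      v <- vl[1]
      yes_a <- sum(as.character(a[[v]]) == vl[2], na.rm = TRUE)
      yes_b <- sum(as.character(b[[v]]) == vl[2], na.rm = TRUE)
      n_a <- sum(!is.na(a[[v]]))
      n_b <- sum(!is.na(b[[v]]))
      cs <- chi_square(matrix(c(yes_a, yes_b, n_a - yes_a, n_b - yes_b), nrow = 2))
      tibble::tibble(variable = v, test = "chi_square", statistic = cs$chi2,
                     dof = cs$dof, p_value = cs$p_value)
    }))
  dplyr::mutate(dplyr::bind_rows(cont, cat_),
                contrast = paste(target_group, "vs", reference_group),
                .before = 1)
}

#' Render resampling summaries in the standard table layout
#'
#' Formats one row per summary with the column order Model, Groups, Median
#' effect size, Median T stat, Lower/Upper 99.5% CI, Lower/Upper 95% CI, all
#' rounded to 2 decimals (full precision lives in the trace files), plus a
#' significance footnote marker: `*` when the 95% CI of the t-statistic
#' excludes zero, `**` when the 99.5% CI does too.
#'
#' @param summaries A `resample_summary`, or a list of them.
#' @return A tibble of formatted character columns.
#' @export
render_summary_table <- function(summaries) {
  if (inherits(summaries, "resample_summary")) summaries <- list(summaries)
  if (length(summaries) == 0L) {
    rlang::abort("no summaries to render", class = "wmhboot_config_error")
  }
  fmt <- function(x) sprintf("%.2f", x)
  dplyr::bind_rows(lapply(summaries, function(s) {
    stopifnot(inherits(s, "resample_summary"))
    tibble::tibble(
      model = s$model_id,
      groups = s$contrast,
      median_effect_size = fmt(s$median_effect),
      median_t_stat = fmt(s$median_t),
      lower_ci_995 = fmt(s$ci995_t[1]),
      upper_ci_995 = fmt(s$ci995_t[2]),
      lower_ci_95 = fmt(s$ci95_t[1]),
      upper_ci_95 = fmt(s$ci95_t[2]),
      significance = paste0(if (s$excludes_zero_95) "*" else "",
                            if (s$excludes_zero_995) "*" else "")
    )
  }))
}
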