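# Covariate-matched subsampling of the larger (reference) group.
#
# The matching design: exact stratification on sex x diagnosis (each cell's
# selected reference count equals its target count), then within each cell
# randomised k-nearest-neighbour matching without replacement on jointly
# standardised (age, education): targets are visited in a shuffled order and
# each draws one reference participant uniformly at random among its
# `k_nearest` nearest still-available candidates. The uniform draw among the
# k nearest keeps genuine resampling variability across iterations -- a
# deterministic nearest-neighbour rule would select nearly the same
# reference participants every iteration and collapse the spread of the
# bootstrap t-distribution -- while the k-nearest bound keeps matched pairs
# close. `k_nearest = 1` degenerates to the pure greedy nearest-neighbour
# rule (deterministic up to target order and ties).

match_vars_continuous <- c("age", "education")
match_vars_categorical <- c("sex", "diagnosis")

# Precompute everything seed-independent for matching one contrast.
match_context <- function(cohort, reference_group, target_group, group_col = "group") {
  check_cohort(cohort)
  base <- baseline_rows(cohort)
  base$.row <- which(cohort$time_from_baseline_days == 0)
  if (anyDuplicated(base$id)) {
    rlang::abort("duplicate participant identifiers among baseline rows",
                 class = "wmhboot_schema_error")
  }
  g <- base[[group_col]]
  for (lab in c(reference_group, target_group)) {
    if (!any(g == lab)) {
      rlang::abort(sprintf("group '%s' not present in column '%s'", lab, group_col),
                   class = "wmhboot_schema_error")
    }
  }
  ref <- base[g == reference_group, ]
  tgt <- base[g == target_group, ]
  # standardise continuous matching variables by reference-pool SDs
  sds <- vapply(match_vars_continuous, function(v) stats::sd(ref[[v]]), 0)
  sds[!is.finite(sds) | sds == 0] <- 1
  cell_of <- function(d) paste(d$sex, d$diagnosis, sep = "/")
  ref_cell <- cell_of(ref)
  tgt_cell <- cell_of(tgt)
  scale_mat <- function(d) {
    m <- as.matrix(d[match_vars_continuous])
    sweep(m, 2, sds, "/")
  }
  ref_x <- scale_mat(ref)
  tgt_x <- scale_mat(tgt)
  ref_cells <- split(seq_len(nrow(ref)), ref_cell)
  tgt_cells <- split(seq_len(nrow(tgt)), tgt_cell)
  # per target, candidates of its stratum ranked by distance once: every
  # iteration then only needs to skip already-taken candidates
  rank_cells <- lapply(names(tgt_cells), function(cell) {
    t_idx <- tgt_cells[[cell]]
    c_idx <- ref_cells[[cell]]
    if (is.null(c_idx) || length(c_idx) == 0L) return(NULL)
    cx1 <- ref_x[c_idx, 1L]
    cx2 <- ref_x[c_idx, 2L]
    lapply(t_idx, function(j) {
      d <- (cx1 - tgt_x[j, 1L])^2 + (cx2 - tgt_x[j, 2L])^2
      order(d)
    })
  })
  names(rank_cells) <- names(tgt_cells)
  list(reference_group = reference_group, target_group = target_group,
       group_col = group_col,
       ref = ref, tgt = tgt,
       ref_x = ref_x, tgt_x = tgt_x,
       ref_cells = ref_cells, tgt_cells = tgt_cells,
       rank_cells = rank_cells)
}

# One seeded matched selection from a prebuilt context. Returns positions
# into ctx$ref plus the per-cell report.
match_select <- function(ctx, seed, k_nearest = 10L, replace_infeasible = FALSE) {
  set.seed(seed)
  selected <- integer(0)
  cells <- names(ctx$tgt_cells)
  rep_target <- rep_cand <- integer(length(cells))
  rep_wr <- logical(length(cells))
  for (ci in seq_along(cells)) {
    cell <- cells[ci]
    t_idx <- ctx$tgt_cells[[cell]]
    c_idx <- ctx$ref_cells[[cell]]
    n_t <- length(t_idx)
    n_c <- length(c_idx)
    if (n_c < n_t) {
      if (!replace_infeasible) {
        rlang::abort(
          sprintf("matching infeasible in stratum sex/diagnosis = %s: %d reference candidates for %d targets",
                  cell, n_c, n_t),
          class = "wmhboot_matching_error"
        )
      }
      if (n_c == 0L) {
        rlang::abort(
          sprintf("matching impossible in stratum sex/diagnosis = %s: no reference candidates", cell),
          class = "wmhboot_matching_error"
        )
      }
      rlang::warn(sprintf("stratum %s: sampling reference participants with replacement (%d candidates < %d targets)",
                          cell, n_c, n_t))
      sel <- c_idx[sample.int(n_c, n_t, replace = TRUE)]
      selected <- c(selected, sel)
      rep_target[ci] <- n_t; rep_cand[ci] <- n_c; rep_wr[ci] <- TRUE
      next
    }
    ranks <- ctx$rank_cells[[cell]]
    perm <- sample.int(n_t)
    taken <- rep(FALSE, n_c)
    sel <- integer(n_t)
    n_avail <- n_c
    for (j in perm) {
      v <- ranks[[j]]
      free <- v[!taken[v]]
      kk <- min(k_nearest, n_avail)
      # uniform draw among the k nearest available: keeps resampling
      # variability without sacrificing match quality
      pick <- free[if (kk > 1L) sample.int(kk, 1L) else 1L]
      taken[pick] <- TRUE
      n_avail <- n_avail - 1L
      sel[j] <- c_idx[pick]
    }
    selected <- c(selected, sel)
    rep_target[ci] <- n_t; rep_cand[ci] <- n_c
  }
  list(selected = selected,
       report = list(cell = cells, target_count = rep_target,
                     candidate_count = rep_cand, selected_count = rep_target,
                     with_replacement = rep_wr))
}

smd_continuous <- function(x_t, x_r) {
  v_t <- stats::var(x_t)
  v_r <- stats::var(x_r)
  if (!is.finite(v_t)) v_t <- NA_real_
  if (!is.finite(v_r)) v_r <- NA_real_
  pooled <- sqrt((v_t + v_r) / 2)
  dm <- mean(x_t) - mean(x_r)
  if (!is.finite(pooled) || pooled == 0) {
    if (isTRUE(all.equal(dm, 0))) 0 else NA_real_
  } else {
    dm / pooled
  }
}

balance_table <- function(tgt, ref_sel, ref_pool) {
  rows <- list()
  for (v in match_vars_continuous) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, level = NA_character_, type = "smd",
      pre = smd_continuous(tgt[[v]], ref_pool[[v]]),
      post = smd_continuous(tgt[[v]], ref_sel[[v]])
    )
  }
  prop_diff <- function(var, lev) {
    tibble::tibble(
      variable = var, level = lev, type = "prop_diff",
      pre = mean(tgt[[var]] == lev) - mean(ref_pool[[var]] == lev),
      post = mean(tgt[[var]] == lev) - mean(ref_sel[[var]] == lev)
    )
  }
  rows[[length(rows) + 1L]] <- prop_diff("sex", "male")
  for (lev in c("NC", "MCI", "AD")) {
    rows[[length(rows) + 1L]] <- prop_diff("diagnosis", lev)
  }
  dplyr::bind_rows(rows)
}

#' Build one covariate-matched subsample of the reference group
#'
#' Selects, at participant (baseline-row) level, a subsample of the
#' reference group of exactly the target group's size, exactly balanced on
#' the sex x diagnosis strata and greedily matched on standardised age and
#' education within each stratum (see the design notes in the package
#' vignette). One call corresponds to one bootstrap iteration.
#'
#' @param cohort A participant-visit cohort table.
#' @param reference_group,target_group Group labels; the reference group is
#'   subsampled to match the target group.
#' @param seed Integer seed for this iteration.
#' @param group_col Column holding the group labels (`"group"` or
#'   `"ethnicity"`).
#' @param k_nearest The matched reference participant is drawn uniformly at
#'   random among the target's `k_nearest` nearest available candidates.
#'   `k_nearest = 1` gives the pure greedy nearest-neighbour rule
#'   (deterministic up to target order and ties).
#' @param replace_infeasible If `TRUE`, a stratum with fewer candidates than
#'   targets is filled by sampling with replacement (with a warning) instead
#'   of erroring.
#' @return An object of class `match_plan` with elements `reference_ids`,
#'   `target_ids`, `reference_rows`/`target_rows` (row indices of baseline
#'   rows in `cohort`), `strata_report`, `balance`, and `iteration_seed`.
#' @export
#' @examples
#' cfg <- generator_config(clinical_cohort_profiles(scale = 0.05), seed = 7)
#' cohort <- cohort_baseline(cfg)
#' plan <- match_subsample(cohort, "White", "Black", seed = 1)
#' plan$strata_report
match_subsample <- function(cohort, reference_group, target_group, seed,
                            group_col = "group", k_nearest = 10L,
                            replace_infeasible = FALSE) {
  check_number(seed, "seed")
  check_number(k_nearest, "k_nearest", lower = 1)
  ctx <- match_context(cohort, reference_group, target_group, group_col)
  res <- match_select(ctx, seed, k_nearest, replace_infeasible)
  new_match_plan(ctx, res, seed, k_nearest)
}

new_match_plan <- function(ctx, res, seed, k_nearest) {
  ref_sel <- ctx$ref[res$selected, ]
  structure(
    list(
      iteration_seed = as.integer(seed),
      reference_group = ctx$reference_group,
      target_group = ctx$target_group,
      group_col = ctx$group_col,
      k_nearest = k_nearest,
      reference_ids = ref_sel$id,
      target_ids = ctx$tgt$id,
      reference_rows = ref_sel$.row,
      target_rows = ctx$tgt$.row,
      strata_report = tibble::as_tibble(res$report),
      balance = balance_table(ctx$tgt, ref_sel, ctx$ref)
    ),
    class = "match_plan"
  )
}

#' @export
print.match_plan <- function(x, ...) {
  cat(sprintf("<match_plan> %s matched to %s (n = %d), iteration seed %d\n",
              x$reference_group, x$target_group, length(x$target_ids),
              x$iteration_seed))
  cat("strata:\n")
  print(x$strata_report)
  cat("balance (standardised mean / proportion differences):\n")
  print(x$balance)
  invisible(x)
}

#' Pre- and post-match balance diagnostics for a match plan
#'
#' Standardised mean differences (difference of means over the pooled SD)
#' for age and education, and raw proportion differences for sex and each
#' diagnosis level, comparing the target group against the full reference
#' pool (`pre`) and against the selected subsample (`post`).
#'
#' @param cohort The cohort the plan was built on.
#' @param plan A [match_subsample()] result.
#' @return A tibble with columns `variable`, `level`, `type`, `pre`, `post`.
#' @export
balance_diagnostics <- function(cohort, plan) {
  stopifnot(inherits(plan, "match_plan"))
  check_cohort(cohort)
  if (length(plan$reference_rows) == 0L) {
    rlang::abort("match plan has an empty selection", class = "wmhboot_matching_error")
  }
  base <- baseline_rows(cohort)
  g <- base[[plan$group_col]]
  tgt <- base[base$id %in% plan$target_ids, ]
  ref_pool <- base[g == plan$reference_group, ]
  ref_sel <- cohort[plan$reference_rows, ]
  balance_table(tgt, ref_sel, ref_pool)
}

#' Expand a participant-level match plan to all visit rows
#'
#' Returns every visit row of the selected reference participants and of all
#' target-group participants, for use in longitudinal models. Participants
#' selected more than once (with-replacement fallback) contribute their
#' visit rows once per selection.
#'
#' @param cohort The cohort the plan was built on.
#' @param plan A [match_subsample()] result.
#' @return A participant-visit tibble restricted to the matched sample.
#' @export
expand_to_visits <- function(cohort, plan) {
  stopifnot(inherits(plan, "match_plan"))
  check_cohort(cohort)
  idx_by_id <- split(seq_len(nrow(cohort)), cohort$id)
  ids <- c(plan$target_ids, plan$reference_ids)
  missing_ids <- setdiff(unique(ids), names(idx_by_id))
  if (length(missing_ids) > 0L) {
    rlang::abort(sprintf("ids in plan but not in cohort: %s",
                         paste(utils::head(missing_ids, 5), collapse = ", ")),
                 class = "wmhboot_schema_error")
  }
  cohort[unlist(idx_by_id[ids], use.names = FALSE), ]
}

#' Serialise a match plan to JSON for audit
#'
#' @param plan A [match_subsample()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_match_plan <- function(plan, path) {
  stopifnot(inherits(plan, "match_plan"))
  x <- unclass(plan)
  x$strata_report <- as.data.frame(x$strata_report)
  x$balance <- as.data.frame(x$balance)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
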