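# ggplot2 displays of matching balance and resampling distributions.

#' Plot the bootstrap t-statistic distribution of a contrast
#'
#' Histogram of the per-iteration t-statistics with the median and the 95% /
#' 99.5% percentile interval bounds marked.
#'
#' @param object A `resample_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot resample_summary
#' @export
autoplot.resample_summary <- function(object, ...) {
  tr <- dplyr::filter(object$trace, .data$ok)
  lines <- tibble::tibble(
    x = c(object$median_t, object$ci95_t, object$ci995_t),
    what = c("median", "95% CI", "95% CI", "99.5% CI", "99.5% CI")
  )
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey35") +
    ggplot2::geom_vline(data = lines,
                        ggplot2::aes(xintercept = .data$x, linetype = .data$what)) +
    ggplot2::geom_vline(xintercept = 0, colour = "red3", alpha = 0.5) +
    ggplot2::labs(x = "t-statistic across iterations", y = "iterations",
                  linetype = NULL,
                  title = sprintf("%s | %s", object$model_id, object$contrast)) +
    ggplot2::theme_minimal()
}

#' Forest plot of a regional panel or any set of resampling summaries
#'
#' Median t-statistic with 95% (thick) and 99.5% (thin) percentile
#' intervals, one row per model.
#'
#' @param object A `wmh_panel` (or list of `resample_summary`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wmh_panel
#' @export
autoplot.wmh_panel <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(y = .data$model, x = .data$median_t)) +
    ggplot2::geom_vline(xintercept = 0, colour = "red3", alpha = 0.5) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$ci995_lower,
                                         xmax = .data$ci995_upper),
                            linewidth = 0.4) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$ci95_lower,
                                         xmax = .data$ci95_upper),
                            linewidth = 1.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "median t (95% thick, 99.5% thin percentile CI)",
                  y = NULL, title = unique(d$contrast)[1]) +
    ggplot2::theme_minimal()
}

#' Dot plot of pre- vs post-match covariate balance
#'
#' @param plan A [match_subsample()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_balance <- function(plan, ...) {
  stopifnot(inherits(plan, "match_plan"))
  d <- plan$balance |>
    dplyr::mutate(label = ifelse(is.na(.data$level), .data$variable,
                                 paste0(.data$variable, ": ", .data$level))) |>
    tidyr::pivot_longer(c("pre", "post"), names_to = "stage", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$label,
                                  colour = .data$stage)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "standardised mean / proportion difference", y = NULL,
                  colour = NULL,
                  title = sprintf("Balance: %s matched to %s",
                                  plan$reference_group, plan$target_group)) +
    ggplot2::theme_minimal()
}
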