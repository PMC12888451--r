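#' Trace plots for a fitted model
#'
#' Monitored chains for the intercept and the three level variances; a quick
#' visual mixing check to read alongside the ESS table.
#'
#' @param object A [fit_pahc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pahc_fit <- function(object, ...) {
  draws <- tibble::tibble(
    iteration = seq_along(object$beta0_draws),
    beta0 = object$beta0_draws,
    sigma2_cluster = object$sigma2_draws$cluster,
    sigma2_district = object$sigma2_draws$district,
    sigma2_state = object$sigma2_draws$state) |>
    tidyr::pivot_longer(-"iteration", names_to = "parameter")
  ggplot2::ggplot(draws, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(title = sprintf("MCMC traces: %s (%s)", object$outcome,
                                  object$round),
                  x = "monitored iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Distribution of district estimates by outcome and round
#'
#' @param districts A district-estimate tibble (see [district_average()]).
#' @return A ggplot object: one histogram per outcome, rounds overlaid.
#' @export
plot_district_estimates <- function(districts) {
  ggplot2::ggplot(districts,
                  ggplot2::aes(100 * .data$p_hat, fill = .data$round)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.6,
                            position = "identity") +
    ggplot2::facet_wrap(~outcome, scales = "free_x") +
    ggplot2::labs(x = "district prevalence (%)", y = "districts",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Improvement-category counts by outcome
#'
#' @param change_records A tibble from [change_table()].
#' @return A ggplot bar chart of districts per improvement category.
#' @export
plot_change_categories <- function(change_records) {
  ggplot2::ggplot(change_records, ggplot2::aes(.data$category)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = "improvement category", y = "districts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Combination-of-problems shares
#'
#' @param cells A tibble from [combination_table()].
#' @return A ggplot bar chart of the 16 weighted cell percentages per round.
#' @export
plot_combinations <- function(cells) {
  ggplot2::ggplot(cells,
                  ggplot2::aes(stats::reorder(.data$label,
                                              .data$pct_weighted),
                               .data$pct_weighted, fill = .data$round)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           position = "dodge", linewidth = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "weighted % of women", fill = NULL) +
    ggplot2::theme_minimal()
}
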