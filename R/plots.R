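#' Density plot of Monte Carlo replicate means
#'
#' Shows the sampling distribution of the replicate mean ambulance-use rate,
#' optionally with vertical reference lines (e.g. the naive and
#' weighted-naive estimates).
#'
#' @param replicate_means Numeric vector of replicate means.
#' @param references Optional named numeric vector of reference rates to
#'   mark.
#' @return A ggplot object.
#' @export
plot_replicate_means <- function(replicate_means, references = NULL) {
  stopifnot(is.numeric(replicate_means), length(replicate_means) >= 2)
  df <- tibble::tibble(mean_rate = replicate_means)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_rate)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::labs(x = "Replicate mean ambulance-use rate", y = "Density") +
    ggplot2::theme_minimal()
  if (!is.null(references) && length(references) > 0) {
    ref <- tibble::tibble(
      method = names(references) %||% paste0("ref", seq_along(references)),
      rate = unname(references)
    )
    p <- p +
      ggplot2::geom_vline(
        data = ref,
        ggplot2::aes(xintercept = .data$rate, colour = .data$method),
        linetype = "dashed", linewidth = 0.7) +
      ggplot2::labs(colour = "Reference")
  }
  p
}

#' @describeIn monte_carlo_rate Autoplot method: density of the replicate
#'   means with optional reference lines.
#' @param object An `ambulance_rate_estimate` carrying replicate means.
#' @param references Optional named numeric vector of reference rates.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.ambulance_rate_estimate <- function(object, references = NULL, ...) {
  if (is.null(object$replicate_means)) {
    stop("autoplot needs an estimate with replicate means (simulation method)",
         call. = FALSE)
  }
  plot_replicate_means(object$replicate_means, references = references)
}

#' Bar chart of scenario ambulance totals
#'
#' One bar per estimator within each per-capita rate scenario, stacked by
#' period (night/day).
#'
#' @param summary Scenario summary tibble from [build_scenario_table()].
#' @return A ggplot object.
#' @export
plot_demand_summary <- function(summary) {
  check_columns(summary, c("method", "rate_label", "night_total", "day_total"),
                "`summary`")
  long <- tidyr::pivot_longer(
    summary[, c("method", "rate_label", "night_total", "day_total")],
    cols = c("night_total", "day_total"),
    names_to = "period", values_to = "need")
  long$period <- ifelse(long$period == "day_total", "day", "night")
  long$rate_label <- factor(long$rate_label, levels = c("low", "mid", "high"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$need,
                                     fill = .data$period)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~rate_label) +
    ggplot2::labs(x = NULL, y = "Annual ambulance needs", fill = "Period") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
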