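#' Tidy a fitted strategy comparison
#'
#' @param x A `crc_model` from [run_model()].
#' @param ... Unused.
#' @return One row per strategy x measure, long format.
#' @export
tidy.crc_model <- function(x, ...) {
  x$outcomes |>
    tidyr::pivot_longer(-"strategy", names_to = "measure",
                        values_to = "value")
}

#' @describeIn tidy.crc_model One-row model summary: baseline cases and costs,
#'   and each screening strategy's ICER versus the baseline.
#' @export
glance.crc_model <- function(x, ...) {
  base <- x$outcomes[x$outcomes$strategy == x$baseline, ]
  out <- tibble(baseline = x$baseline,
                baseline_cases = base$total_cases,
                baseline_cost = base$total_cost,
                baseline_life_years_lost = base$life_years_lost)
  if (!is.null(x$report)) {
    ic <- stats::setNames(x$report$icer_vs_baseline,
                          paste0("icer_", x$report$strategy))
    out <- dplyr::bind_cols(out, as_tibble(as.list(ic)))
  }
  out
}

#' Cost-effectiveness plane
#'
#' Plots each strategy's discounted total cost against the life-years it
#' saves relative to the baseline.
#'
#' @param object A `crc_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.crc_model <- function(object, ...) {
  base <- object$outcomes[object$outcomes$strategy == object$baseline, ]
  df <- object$outcomes |>
    mutate(life_years_saved = base$life_years_lost - .data$life_years_lost)
  ggplot2::ggplot(df, ggplot2::aes(.data$life_years_saved,
                                   .data$total_cost / 1e6,
                                   label = .data$strategy)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Life-years saved vs baseline",
                  y = "Total discounted cost (USD millions)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Sensitivity-sweep profile plot
#'
#' ICER versus the swept parameter, one line per strategy (the analogue of the
#' published one-way sensitivity figures).
#'
#' @param object A `crc_sweep` from [one_way_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.crc_sweep <- function(object, ...) {
  xcol <- if ("value" %in% names(object)) "value" else "value1"
  ggplot2::ggplot(object, ggplot2::aes(.data[[xcol]], .data$icer_vs_baseline,
                                       colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = object$param[1] %||% object$param1[1],
                  y = "ICER vs no screening (USD per life-year)",
                  colour = "strategy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.crc_model
#' @param model A `crc_model`.
#' @export
plot_ce_plane <- function(model) autoplot(model)

#' @rdname autoplot.crc_sweep
#' @param sweep A `crc_sweep`.
#' @export
plot_sweep <- function(sweep) autoplot(sweep)
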