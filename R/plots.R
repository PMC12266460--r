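#' Plot a cohort trace
#'
#' State occupancancy fractions over time, one line per state.
#'
#' @param object A `cohort_trace` from [run_markov()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cohort_trace
#' @export
autoplot.cohort_trace <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("month", dplyr::all_of(weight_states)) |>
    tidyr::pivot_longer(-"month", names_to = "state",
                        values_to = "occupancy") |>
    dplyr::mutate(state = factor(.data$state, levels = weight_states))
  ggplot2::ggplot(long, ggplot2::aes(.data$month, .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_continuous(labels = scales_percent) +
    ggplot2::labs(x = "Month", y = "Cohort fraction", colour = "State") +
    ggplot2::theme_minimal()
}

scales_percent <- function(x) paste0(round(100 * x, 1), "%")

#' Plot a PSA result on the cost-effectiveness plane
#'
#' Incremental QALYs against incremental cost, one point per replication,
#' with the willingness-to-pay threshold as a dashed line.
#'
#' @param object A `psa_result` from [run_psa()].
#' @param measure `"htvas"` or `"sf36"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psa_result
#' @export
autoplot.psa_result <- function(object, measure = c("htvas", "sf36"), ...) {
  measure <- rlang::arg_match(measure)
  wtp <- attr(object, "wtp")
  df <- tibble::tibble(
    d_qaly = object[[paste0("d_qaly_", measure)]],
    d_cost = object$d_cost,
    cost_effective = object[[paste0("cost_effective_", measure)]]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$d_qaly, .data$d_cost,
                                   colour = .data$cost_effective)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(
      x = sprintf("Incremental QALYs (%s)", toupper(measure)),
      y = "Incremental cost (USD)", colour = "Cost-effective"
    ) +
    ggplot2::theme_minimal()
}

#' Tornado plot of a one-way sensitivity analysis
#'
#' ICER range per varied parameter, ordered by spread, with the base-case
#' ICER as a vertical line.
#'
#' @param object An `owsa_result` from [run_owsa()].
#' @param measure `"htvas"` or `"sf36"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot owsa_result
#' @export
autoplot.owsa_result <- function(object, measure = c("htvas", "sf36"), ...) {
  measure <- rlang::arg_match(measure)
  col <- paste0("icer_", measure)
  base <- object[[col]][object$direction == "base"]
  df <- object |>
    dplyr::filter(.data$direction != "base") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(lo = min(.data[[col]]), hi = max(.data[[col]])) |>
    dplyr::arrange(.data$hi - .data$lo) |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = .data$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$lo, xend = .data$hi, yend = .data$parameter),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = sprintf("ICER, USD/QALY (%s)", toupper(measure)),
                  y = NULL) +
    ggplot2::theme_minimal()
}
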