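#' Per-participant program cost
#'
#' Divides a total delivery cost by the number of participants and rounds to
#' the cent (half-up, as currency).
#'
#' @param total_usd Non-negative total cost.
#' @param n Positive number of participants.
#' @return Cost per participant in USD, to the cent.
#' @examples
#' per_participant_cost(82741.19, 149) # 555.31
#' @export
per_participant_cost <- function(total_usd, n) {
  if (any(n < 1)) rlang::abort("n must be a positive participant count")
  if (any(total_usd < 0)) rlang::abort("total_usd must be non-negative")
  round_cents(total_usd / n)
}

# round half-up to cents (base round() is round-half-even)
round_cents <- function(x) floor(x * 100 + 0.5) / 100

#' Summarise a program delivery cost ledger
#'
#' Aggregates a long line-item ledger (see [default_program_costs()]) into
#' per-arm, per-phase totals and per-participant costs, plus a combined
#' all-phase per-participant cost. Per-participant values are each total
#' divided by the arm size, rounded to the cent.
#'
#' @param program_costs A ledger with columns `arm`, `phase`, `line_item`,
#'   `total_usd`, `n_participants`.
#' @return A tibble with one row per arm: `n_participants`, one
#'   `phase<k>_total` / `phase<k>_per_participant` pair per phase, and
#'   `total`, `per_participant` for all phases combined.
#' @export
summarize_program_costs <- function(program_costs) {
  by_phase <- program_costs |>
    dplyr::group_by(.data$arm, .data$phase) |>
    dplyr::summarise(
      n_participants = unique(.data$n_participants),
      total = sum(.data$total_usd),
      .groups = "drop"
    ) |>
    dplyr::mutate(per_participant = per_participant_cost(.data$total,
                                                         .data$n_participants))
  wide <- by_phase |>
    tidyr::pivot_wider(
      id_cols = c("arm", "n_participants"),
      names_from = "phase",
      values_from = c("total", "per_participant"),
      names_glue = "phase{phase}_{.value}"
    )
  totals <- by_phase |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(total = sum(.data$total),
                     n_participants = unique(.data$n_participants)) |>
    dplyr::mutate(per_participant = per_participant_cost(.data$total,
                                                         .data$n_participants)) |>
    dplyr::select("arm", "total", "per_participant")
  dplyr::left_join(wide, totals, by = "arm")
}

#' Present-value discount factor
#'
#' `(1 + annual_rate)^(-(month - time_zero_month) / 12)`.
#'
#' @param month Time of the payoff, in months from model start.
#' @param annual_rate Annual discount rate (default 0.03).
#' @param time_zero_month Reference month for present value (default 0).
#' @export
discount_factor <- function(month, annual_rate = 0.03, time_zero_month = 0) {
  if (annual_rate < 0 || annual_rate >= 1) {
    rlang::abort("annual_rate must lie in [0, 1)")
  }
  if (any(month < time_zero_month)) {
    rlang::abort("month must not precede time_zero_month")
  }
  (1 + annual_rate)^(-(month - time_zero_month) / 12)
}

#' Total monthly out-of-pocket cost for a state
#'
#' Medication plus other healthcare cost per month for an alive state; the
#' dead state costs 0.
#'
#' @param state_econ A state-economics table (see
#'   [validate_state_economics()]).
#' @param state A state label from [weight_states].
#' @export
monthly_state_cost <- function(state_econ, state) {
  if (identical(state, "dead")) return(0)
  se <- validate_state_economics(state_econ)
  i <- match(state, se$state)
  if (is.na(i)) rlang::abort(sprintf("unknown state '%s'", state))
  se$rx_monthly[i] + se$other_monthly[i]
}

# per-state vectors over weight_states (dead = 0)
state_cost_vector <- function(state_econ) {
  se <- validate_state_economics(state_econ)
  c(se$rx_monthly + se$other_monthly, 0)
}

state_score_vector <- function(state_econ, measure = c("htvas", "sf36")) {
  measure <- rlang::arg_match(measure)
  se <- validate_state_economics(state_econ)
  c(se[[measure]], 0)
}

# Shared accumulation walk: for each stored trace interval clipped to the
# window, returns duration (months), attribution occupancy and discount
# factor. Attribution is at the clipped interval end by default; with
# half_cycle = TRUE the occupancy is the endpoint average and discounting is
# at the interval midpoint.
trace_intervals <- function(trace, window, annual_rate, time_zero_month = 0,
                            half_cycle = FALSE) {
  if (window[1] < min(trace$month) - 1e-9 ||
      window[2] > max(trace$month) + 1e-9) {
    rlang::abort(sprintf(
      "window [%g, %g] is outside the trace (months %g-%g)",
      window[1], window[2], min(trace$month), max(trace$month)
    ))
  }
  occ <- as.matrix(trace[, weight_states])
  t <- trace$month
  out <- vector("list", length(t) - 1)
  for (k in seq_len(length(t) - 1)) {
    lo <- max(t[k], window[1])
    hi <- min(t[k + 1], window[2])
    dur <- hi - lo
    if (dur <= 1e-12) next
    w <- if (half_cycle) (occ[k, ] + occ[k + 1, ]) / 2 else occ[k + 1, ]
    at <- if (half_cycle) (lo + hi) / 2 else hi
    out[[k]] <- list(
      dur = dur, occ = w,
      disc = discount_factor(at, annual_rate, time_zero_month)
    )
  }
  purrr::compact(out)
}

#' Accumulate discounted per-participant costs over a trace window
#'
#' Program delivery costs per participant (undiscounted; incurred within the
#' trial) plus the discounted sum, over every stored trace interval clipped
#' to the window, of the occupancy-weighted monthly state cost times the
#' interval duration. The dead state contributes no cost.
#'
#' @param trace A `cohort_trace`.
#' @param state_econ State-economics table.
#' @param program_per_participant Program cost per participant (USD) to add
#'   undiscounted; 0 for none.
#' @param annual_rate Annual discount rate.
#' @param window Length-2 numeric `(start_month, end_month)`.
#' @param time_zero_month Present-value reference month.
#' @param half_cycle If `TRUE`, attribute each interval at its midpoint with
#'   endpoint-averaged occupancy (half-cycle correction); default `FALSE`,
#'   attribution at interval end.
#' @return Discounted USD per participant.
#' @export
accumulate_costs <- function(trace, state_econ, program_per_participant = 0,
                             annual_rate = 0.03, window = c(0, 70),
                             time_zero_month = 0, half_cycle = FALSE) {
  cost_s <- state_cost_vector(state_econ)
  iv <- trace_intervals(trace, window, annual_rate, time_zero_month, half_cycle)
  oop <- sum(purrr::map_dbl(iv, \(x) x$dur * x$disc * sum(x$occ * cost_s)))
  program_per_participant + oop
}

#' Accumulate discounted QALYs over a trace window
#'
#' Survey scores (0--100) act as utilities after division by 100; each stored
#' trace interval clipped to the window contributes the occupancy-weighted
#' utility times its duration in years, discounted. A 12-month window spent
#' entirely in a state with score 100 yields exactly 1 QALY; the dead state
#' contributes 0.
#'
#' @inheritParams accumulate_costs
#' @param measure `"htvas"` or `"sf36"`.
#' @return Discounted QALYs per participant.
#' @export
accumulate_qalys <- function(trace, state_econ, measure = c("htvas", "sf36"),
                             annual_rate = 0.03, window = c(10, 70),
                             time_zero_month = 0, half_cycle = FALSE) {
  u_s <- state_score_vector(state_econ, measure) / 100
  iv <- trace_intervals(trace, window, annual_rate, time_zero_month, half_cycle)
  sum(purrr::map_dbl(iv, \(x) (x$dur / 12) * x$disc * sum(x$occ * u_s)))
}
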