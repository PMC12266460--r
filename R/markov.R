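#' Run a Markov cohort model over a transition schedule
#'
#' Propagates a cohort's state-occupancy distribution through the observed
#' trial segments, then applies the schedule's extrapolation matrix once per
#' 6-month cycle up to the horizon. The trace stores every segment endpoint
#' and every post-trial cycle; no interpolation is performed between stored
#' times.
#'
#' @param initial Length-4 probability vector over [weight_states] (sums to 1).
#' @param schedule A [transition_schedule()].
#' @param horizon_months Total horizon from month 0; must reach at least the
#'   end of the last observed segment. Default 70 (a 22-month trial followed
#'   by eight 6-month cycles).
#' @param cohort_size Presentation scaling for expected counts (default
#'   100000); does not affect the occupancy fractions.
#' @return A `cohort_trace`: a tibble with columns `month`, one occupancy
#'   column per state, and expected counts `n_<state>` scaled by
#'   `cohort_size`.
#' @examples
#' m <- transition_matrix(rbind(
#'   c(0.5, 0.3, 0.2, 0), c(0.2, 0.6, 0.2, 0),
#'   c(0.1, 0.2, 0.7, 0), c(0, 0, 0, 1)
#' ), 6)
#' sched <- transition_schedule(list(m), m)
#' run_markov(c(1, 0, 0, 0), sched, horizon_months = 24)
#' @export
run_markov <- function(initial, schedule, horizon_months = 70,
                       cohort_size = 100000) {
  if (length(initial) != 4L || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-9) {
    rlang::abort("initial must be a length-4 probability vector summing to 1")
  }
  if (!inherits(schedule, "transition_schedule")) {
    rlang::abort("schedule must be a transition_schedule")
  }
  seg <- schedule$segments
  last_end <- max(seg$end_month)
  if (horizon_months < last_end) {
    rlang::abort(sprintf(
      "horizon_months (%g) must reach the last observed segment (month %g)",
      horizon_months, last_end
    ))
  }
  times <- seg$start_month[1]
  occ <- matrix(initial, nrow = 1)
  state <- initial
  for (k in seq_len(nrow(seg))) {
    state <- as.numeric(state %*% unclass(seg$matrix[[k]]))
    times <- c(times, seg$end_month[k])
    occ <- rbind(occ, state)
  }
  post <- seq(last_end + 6, horizon_months, by = 6)
  for (t in post) {
    state <- as.numeric(state %*% unclass(schedule$extrapolation))
    times <- c(times, t)
    occ <- rbind(occ, state)
  }
  colnames(occ) <- weight_states
  trace <- tibble::as_tibble(as.data.frame(occ))
  trace <- dplyr::mutate(trace, month = times, .before = 1)
  for (s in weight_states) trace[[paste0("n_", s)]] <- trace[[s]] * cohort_size
  structure(trace,
    cohort_size = cohort_size,
    class = c("cohort_trace", class(trace))
  )
}

#' Occupancy vector at a stored trace time
#'
#' Returns the exact stored occupancy vector; months between stored times are
#' an error (no interpolation), with the available times listed.
#'
#' @param trace A `cohort_trace` from [run_markov()].
#' @param month A stored month.
#' @return Named length-4 numeric vector over [weight_states].
#' @export
occupancy_at <- function(trace, month) {
  i <- which(abs(trace$month - month) < 1e-9)
  if (length(i) != 1L) {
    rlang::abort(sprintf(
      "month %g is not stored in the trace; available: %s",
      month, paste(trace$month, collapse = ", ")
    ))
  }
  v <- as.numeric(trace[i, weight_states])
  names(v) <- weight_states
  v
}

#' Empirical state occupancy of a cohort at an assessment month
#'
#' The fraction of records (with observed weights) in each alive state at the
#' given month; `dead` is 0 by construction (no within-trial mortality is
#' recorded in the cohort format).
#'
#' @param cohort A cohort data frame.
#' @param month Assessment month (0, 4, 16 or 22).
#' @return Named length-4 numeric vector over [weight_states].
#' @export
empirical_occupancy <- function(cohort, month) {
  w <- weight_at(cohort, month)
  ok <- !is.na(cohort$weight_m0) & !is.na(w)
  st <- factor(categorize_weight(cohort$weight_m0[ok], w[ok]),
               levels = alive_states)
  v <- c(as.numeric(table(st)) / sum(ok), 0)
  names(v) <- weight_states
  v
}
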