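#' Construct a transition matrix
#'
#' A transition matrix is a 4x4 row-stochastic matrix over
#' [weight_states], with the `dead` row fixed at the identity row (death is
#' the only absorbing state), carrying the time interval it spans as the
#' `interval_months` attribute.
#'
#' @param entries A 4x4 numeric matrix, rows = origin states, columns =
#'   destination states, in [weight_states] order.
#' @param interval_months Positive duration (months) the matrix spans.
#' @return A `transition_matrix` object.
#' @export
transition_matrix <- function(entries, interval_months) {
  entries <- as.matrix(entries)
  if (!all(dim(entries) == c(4L, 4L))) {
    rlang::abort("a transition matrix must be 4x4")
  }
  dimnames(entries) <- list(weight_states, weight_states)
  if (!is.numeric(interval_months) || length(interval_months) != 1L ||
      interval_months <= 0) {
    rlang::abort("interval_months must be a single positive number")
  }
  out <- structure(entries,
    interval_months = as.numeric(interval_months),
    class = c("transition_matrix", "matrix", "array")
  )
  validate_transition_matrix(out)
  out
}

validate_transition_matrix <- function(m, tol = 1e-9) {
  if (any(m < -tol) || any(m > 1 + tol)) {
    rlang::abort("transition probabilities must lie in [0, 1]")
  }
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol)) {
    rlang::abort(sprintf(
      "rows must sum to 1 within %g (max deviation %g)", tol, max(abs(rs - 1))
    ))
  }
  if (!isTRUE(all.equal(unname(m["dead", ]), c(0, 0, 0, 1), tolerance = tol))) {
    rlang::abort("the dead row must be absorbing: (0, 0, 0, 1)")
  }
  invisible(m)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition matrix, %g-month interval>\n",
              attr(x, "interval_months")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Months spanned by a transition matrix
#' @param m A `transition_matrix`.
#' @export
interval_months <- function(m) attr(m, "interval_months")

#' Estimate an empirical transition matrix between two assessment months
#'
#' Each entry (i, j) is the proportion of participants observed in state i at
#' `from_month` that are in state j at `to_month`; the denominator counts
#' participants in state i at `from_month` with weights observed at both
#' months. The dead row is forced absorbing. An origin state with no
#' participants gets a self-loop row (probability 1 of staying), with a
#' warning, so the result stays row-stochastic.
#'
#' @param cohort A cohort data frame (see [simulate_cohort()]) with columns
#'   `weight_m0` and `weight_m<from_month>` / `weight_m<to_month>`.
#' @param from_month,to_month Assessment months, e.g. 16 and 22.
#' @param warn_empty Warn when an origin state is empty (default `TRUE`);
#'   pass `FALSE` where emptiness is structural (e.g. month 0, where every
#'   participant is at baseline weight).
#' @return A [transition_matrix()] with `interval_months = to_month - from_month`.
#' @export
estimate_transition_matrix <- function(cohort, from_month, to_month,
                                       warn_empty = TRUE) {
  if (to_month <= from_month) rlang::abort("to_month must exceed from_month")
  wf <- weight_at(cohort, from_month)
  wt <- weight_at(cohort, to_month)
  ok <- !is.na(cohort$weight_m0) & !is.na(wf) & !is.na(wt)
  if (!any(ok)) {
    rlang::abort(sprintf(
      "no records with weights at both month %s and month %s",
      from_month, to_month
    ))
  }
  sf <- factor(categorize_weight(cohort$weight_m0[ok], wf[ok]),
               levels = alive_states)
  st <- factor(categorize_weight(cohort$weight_m0[ok], wt[ok]),
               levels = alive_states)
  counts <- table(sf, st)
  m <- matrix(0, 4, 4, dimnames = list(weight_states, weight_states))
  for (i in alive_states) {
    n_i <- sum(counts[i, ])
    if (n_i == 0) {
      if (warn_empty) {
        rlang::warn(sprintf(
          "no participants in state '%s' at month %s; using a self-loop row",
          i, from_month
        ))
      }
      m[i, i] <- 1
    } else {
      m[i, alive_states] <- counts[i, ] / n_i
    }
  }
  m["dead", "dead"] <- 1
  transition_matrix(m, to_month - from_month)
}

weight_at <- function(cohort, month) {
  col <- paste0("weight_m", month)
  if (!col %in% names(cohort)) {
    rlang::abort(sprintf("cohort has no column '%s'", col))
  }
  cohort[[col]]
}

#' Convert a 6-month transition matrix to an annual matrix
#'
#' Squares the matrix (two consecutive cycles), doubling the interval.
#'
#' @param m A `transition_matrix` (conventionally a 6-month one).
#' @return A `transition_matrix` spanning twice the interval.
#' @export
to_annual <- function(m) {
  validate_transition_matrix(m)
  out <- unclass(m) %*% unclass(m)
  out["dead", ] <- c(0, 0, 0, 1)  # guard accumulated rounding
  transition_matrix(out, 2 * interval_months(m))
}

#' Rescale a probability to a different time horizon
#'
#' Constant-hazard conversion: `1 - (1 - p)^(to_years / from_years)`. Used to
#' turn an annual mortality probability into a 6-month cycle probability and
#' back.
#'
#' @param p Probability in \[0, 1\].
#' @param from_years,to_years Positive horizons (any common unit).
#' @export
rescale_probability <- function(p, from_years, to_years) {
  if (any(p < 0 | p > 1)) rlang::abort("p must lie in [0, 1]")
  if (from_years <= 0 || to_years <= 0) rlang::abort("horizons must be positive")
  1 - (1 - p)^(to_years / from_years)
}

#' Overlay background mortality on a transition matrix
#'
#' Treats death as a competing risk applied uniformly to all alive states:
#' each alive row is scaled by `1 - cycle_death_prob` over its alive
#' destinations and `cycle_death_prob` is added to its dead column. The dead
#' row is untouched.
#'
#' @param m A `transition_matrix`.
#' @param cycle_death_prob Per-cycle death probability in \[0, 1\].
#' @export
apply_mortality <- function(m, cycle_death_prob) {
  validate_transition_matrix(m)
  if (cycle_death_prob < 0 || cycle_death_prob > 1) {
    rlang::abort("cycle_death_prob must lie in [0, 1]")
  }
  out <- unclass(m)
  out[alive_states, ] <- out[alive_states, ] * (1 - cycle_death_prob)
  out[alive_states, "dead"] <- out[alive_states, "dead"] + cycle_death_prob
  transition_matrix(out, interval_months(m))
}

#' Build a transition schedule
#'
#' A schedule is an ordered list of contiguous observed segments starting at
#' month 0, each with its empirical transition matrix, plus an extrapolation
#' matrix (interval = one 6-month cycle) applied for every cycle past the
#' last segment.
#'
#' @param segments A list of `transition_matrix` objects, in time order; the
#'   k-th segment spans from the cumulative end of the previous segments.
#' @param extrapolation A `transition_matrix` with a 6-month interval, used
#'   for all post-trial cycles.
#' @param start_month Month at which the first segment starts (default 0).
#' @return A `transition_schedule` object.
#' @export
transition_schedule <- function(segments, extrapolation, start_month = 0) {
  stopifnot(length(segments) >= 1)
  purrr::walk(segments, validate_transition_matrix)
  validate_transition_matrix(extrapolation)
  if (abs(interval_months(extrapolation) - 6) > 1e-9) {
    rlang::abort("the extrapolation matrix must span a 6-month cycle")
  }
  ends <- start_month + cumsum(purrr::map_dbl(segments, interval_months))
  starts <- c(start_month, ends[-length(ends)])
  structure(
    list(
      segments = tibble::tibble(
        start_month = starts, end_month = ends, matrix = segments
      ),
      extrapolation = extrapolation
    ),
    class = "transition_schedule"
  )
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat(sprintf(
    "<transition schedule: %d observed segment(s) over months %g-%g, then 6-month extrapolation>\n",
    nrow(x$segments), min(x$segments$start_month), max(x$segments$end_month)
  ))
  invisible(x)
}

#' Tidy a set of per-arm transition matrices into long format
#'
#' @param matrices A named list (by arm) of lists of `transition_matrix`
#'   objects, each inner list named by `"<from>_<to>"` month pairs, or a
#'   single `transition_matrix`.
#' @param arm,from_month,to_month Used when tidying a single matrix.
#' @return A tibble with columns `arm`, `from_month`, `to_month`,
#'   `from_state`, `to_state`, `probability`.
#' @export
tidy_transitions <- function(matrices, arm = NA_character_,
                             from_month = NA_real_, to_month = NA_real_) {
  if (inherits(matrices, "transition_matrix")) {
    m <- matrices
    return(tibble::tibble(
      arm = arm,
      from_month = from_month,
      to_month = to_month,
      from_state = rep(weight_states, each = 4L),
      to_state = rep(weight_states, times = 4L),
      probability = as.vector(t(unclass(m)))
    ))
  }
  purrr::imap_dfr(matrices, function(per_arm, arm_name) {
    purrr::imap_dfr(per_arm, function(m, span) {
      months <- as.numeric(strsplit(span, "_", fixed = TRUE)[[1]])
      tidy_transitions(m, arm = arm_name,
                       from_month = months[1], to_month = months[2])
    })
  })
}
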