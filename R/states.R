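#' Weight-loss model states
#'
#' The cohort model tracks four mutually exclusive states defined by percent
#' weight reduction from baseline: `lt5` (limited or no weight loss, under 5%
#' below baseline, including weight gain), `m5_10` (moderate loss, 5--10%
#' below baseline, both endpoints inclusive), `gt10` (large loss, more than
#' 10% below baseline) and `dead` (death or loss to follow-up, the single
#' absorbing state).
#'
#' @format A character vector of the four state labels, in model order.
#' @export
weight_states <- c("lt5", "m5_10", "gt10", "dead")

#' Alive (transient) states
#' @rdname weight_states
#' @export
alive_states <- c("lt5", "m5_10", "gt10")

#' Categorize weight change into a model state
#'
#' Computes the fractional weight loss `(baseline - current) / baseline` and
#' bins it: loss below 5% (including any gain) is `lt5`, loss of 5--10%
#' inclusive is `m5_10`, and loss above 10% is `gt10`. Ties at the printed
#' 5% and 10% category endpoints go to the moderate bin.
#'
#' @param baseline_kg Baseline weight in kg (positive).
#' @param current_kg Current weight in kg (positive). Vectorised; `NA`
#'   propagates.
#' @return A character vector of state labels (`NA` where `current_kg` is
#'   missing).
#' @examples
#' categorize_weight(100, c(99, 95, 89.9))
#' @export
categorize_weight <- function(baseline_kg, current_kg) {
  if (any(!is.na(baseline_kg) & baseline_kg <= 0) ||
      any(!is.na(current_kg) & current_kg <= 0)) {
    rlang::abort("weights must be strictly positive")
  }
  loss <- (baseline_kg - current_kg) / baseline_kg
  out <- ifelse(loss < 0.05, "lt5", ifelse(loss <= 0.10, "m5_10", "gt10"))
  out[is.na(current_kg) | is.na(baseline_kg)] <- NA_character_
  out
}
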