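#' Packaged base-case inputs
#'
#' The package ships the published base-case inputs of the telephone-coaching
#' weight-maintenance trial as plain-CSV fixtures:
#' `default_state_economics()` returns the state-conditional mean survey
#' scores (HT-VAS and SF-36 general health, 0--100) and mean self-reported
#' monthly out-of-pocket medication (`rx_monthly`) and other healthcare costs
#' (`other_monthly`, constant USD) for the three alive states;
#' `default_program_costs()` returns the per-arm, per-phase program delivery
#' cost ledger (line items, totals and arm sizes); and
#' `default_occupancy_targets()` returns the observed end-of-phase state
#' occupancies by arm at months 16 and 22.
#'
#' @return A tibble (see the individual descriptions).
#' @name fixtures
NULL

read_fixture <- function(name, cols) {
  path <- system.file("extdata", name, package = "weightcea", mustWork = TRUE)
  readr::read_csv(path, col_types = cols, progress = FALSE)
}

#' @rdname fixtures
#' @export
default_state_economics <- function() {
  read_fixture("state_econ.csv", readr::cols(
    state = readr::col_character(), .default = readr::col_double()
  ))
}

#' @rdname fixtures
#' @export
default_program_costs <- function() {
  read_fixture("program_costs.csv", readr::cols(
    arm = readr::col_character(), phase = readr::col_integer(),
    line_item = readr::col_character(), total_usd = readr::col_double(),
    n_participants = readr::col_integer()
  ))
}

#' @rdname fixtures
#' @export
default_occupancy_targets <- function() {
  read_fixture("occupancy_targets.csv", readr::cols(
    arm = readr::col_character(), month = readr::col_integer(),
    .default = readr::col_double()
  ))
}

#' Validate a state-economics table
#'
#' Checks the columns, the state set, score bounds and cost signs; the dead
#' state implicitly contributes zero cost and zero utility everywhere.
#'
#' @param state_econ A data frame with columns `state`, `htvas`, `sf36`,
#'   `rx_monthly`, `other_monthly` and one row per alive state.
#' @return The validated tibble, rows ordered as [alive_states], invisibly
#'   usable downstream.
#' @export
validate_state_economics <- function(state_econ) {
  need <- c("state", "htvas", "sf36", "rx_monthly", "other_monthly")
  miss <- setdiff(need, names(state_econ))
  if (length(miss) > 0) {
    rlang::abort(paste("state_econ is missing columns:",
                       paste(miss, collapse = ", ")))
  }
  if (!setequal(state_econ$state, alive_states)) {
    rlang::abort("state_econ must have exactly one row per alive state")
  }
  scores <- unlist(state_econ[, c("htvas", "sf36")])
  if (any(scores < 0 | scores > 100)) {
    rlang::abort("survey scores must lie in [0, 100]")
  }
  if (any(unlist(state_econ[, c("rx_monthly", "other_monthly")]) < 0)) {
    rlang::abort("monthly costs must be non-negative")
  }
  state_econ <- tibble::as_tibble(state_econ)
  state_econ[match(alive_states, state_econ$state), ]
}
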