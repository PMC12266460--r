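#' Analysis run configuration
#'
#' Collects the model settings shared across the pipeline: the 6-month cycle
#' length is fixed by the model design; the horizon must lie a whole number
#' of cycles past the month-22 end of trial. The default annual mortality /
#' loss-to-follow-up probability is calibrated so the 5-year cumulative risk
#' is 4.3% (`1 - 0.957^(1/5)`), applied to all alive states post-trial.
#'
#' @param annual_rate Annual discount rate (default 0.03).
#' @param wtp Willingness-to-pay threshold, USD/QALY (default 150000).
#' @param horizon_months Model horizon from month 0 (default 70: the
#'   22-month trial plus eight 6-month cycles).
#' @param annual_mortality_prob Annual probability of the absorbing state.
#' @param qaly_window_start First month of the end-of-trial QALY window
#'   (default 10, so the month-22 window spans 12 months and a perfect-health
#'   year is 1 QALY).
#' @param half_cycle Use half-cycle (midpoint) attribution in the
#'   accumulators (default `FALSE`).
#' @param seed Base seed for stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(annual_rate = 0.03, wtp = 150000, horizon_months = 70,
                       annual_mortality_prob = 1 - 0.957^(1 / 5),
                       qaly_window_start = 10, half_cycle = FALSE,
                       seed = 1L) {
  if (horizon_months < 22 || abs((horizon_months - 22) %% 6) > 1e-9) {
    rlang::abort(
      "horizon_months must be 22 plus a whole number of 6-month cycles"
    )
  }
  if (annual_mortality_prob < 0 || annual_mortality_prob >= 1) {
    rlang::abort("annual_mortality_prob must lie in [0, 1)")
  }
  structure(
    list(
      annual_rate = annual_rate, wtp = wtp,
      horizon_months = horizon_months,
      annual_mortality_prob = annual_mortality_prob,
      cycle_months = 6,
      qaly_window_start = qaly_window_start,
      half_cycle = half_cycle, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys match the [run_config()] arguments; unknown
#' keys are an error. An optional `synthetic:` block (passed to
#' [cohort_config()]) is returned in the `synthetic` attribute.
#'
#' @param path Path to a YAML file.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  synth <- raw$synthetic
  raw$synthetic <- NULL
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    rlang::abort(paste("unknown config keys:", paste(bad, collapse = ", ")))
  }
  cfg <- do.call(run_config, raw)
  attr(cfg, "synthetic") <- synth
  cfg
}

#' Fit the full cohort model: transitions, mortality overlay and traces
#'
#' Estimates the three observed-segment transition matrices (months 0--4,
#' 4--16, 16--22) per arm from the cohort, overlays the per-cycle mortality
#' probability (constant-hazard rescaling of the annual probability) on the
#' month-16 to 22 matrix to form the post-trial extrapolation matrix, and
#' propagates each arm's cohort (everyone starts below 5% loss at month 0)
#' to the horizon.
#'
#' @param cohort A cohort tibble or path to a cohort CSV.
#' @param program_costs Program delivery cost ledger (default the packaged
#'   base case).
#' @param state_econ State-economics table (default the packaged base case).
#' @param config A [run_config()].
#' @return A `cea_model` with the per-arm matrices, schedules and traces,
#'   the summarised program costs, the state economics and the config.
#' @export
build_cea_model <- function(cohort,
                            program_costs = default_program_costs(),
                            state_econ = default_state_economics(),
                            config = run_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  cohort <- validate_cohort(cohort)
  state_econ <- validate_state_economics(state_econ)
  program <- summarize_program_costs(program_costs)
  arms <- sort(unique(cohort$arm))
  if (!setequal(program$arm, arms)) {
    rlang::abort("program_costs arms must match the cohort arms")
  }
  cycle_death <- rescale_probability(config$annual_mortality_prob, 1, 0.5)
  initial <- c(1, 0, 0, 0) # everyone starts at baseline weight (< 5% loss)

  fits <- purrr::map(rlang::set_names(arms), function(a) {
    sub <- cohort[cohort$arm == a, ]
    mats <- list(
      `0_4` = estimate_transition_matrix(sub, 0, 4, warn_empty = FALSE),
      `4_16` = estimate_transition_matrix(sub, 4, 16),
      `16_22` = estimate_transition_matrix(sub, 16, 22)
    )
    extrap <- apply_mortality(mats$`16_22`, cycle_death)
    schedule <- transition_schedule(unname(mats), extrap)
    trace <- run_markov(initial, schedule, config$horizon_months)
    list(matrices = mats, extrapolation = extrap, schedule = schedule,
         trace = trace)
  })

  structure(
    list(
      arms = arms,
      matrices = purrr::map(fits, "matrices"),
      extrapolation = purrr::map(fits, "extrapolation"),
      schedules = purrr::map(fits, "schedule"),
      traces = purrr::map(fits, "trace"),
      program = program,
      state_econ = state_econ,
      config = config,
      cycle_death_prob = cycle_death,
      n_per_arm = table(cohort$arm)
    ),
    class = "cea_model"
  )
}

#' @export
print.cea_model <- function(x, ...) {
  cat(sprintf(
    "<cohort CEA model: arms %s; horizon month %g; discount %.0f%%>\n",
    paste(x$arms, collapse = " vs "), x$config$horizon_months,
    100 * x$config$annual_rate
  ))
  invisible(x)
}

# analysis windows for a horizon label
model_windows <- function(config, horizon = c("horizon", "trial")) {
  horizon <- rlang::arg_match(horizon)
  end <- if (horizon == "trial") 22 else config$horizon_months
  list(cost = c(0, end), qaly = c(config$qaly_window_start, end))
}

#' Per-arm accumulated costs and QALYs from a fitted model
#'
#' @param model A `cea_model`.
#' @param horizon `"horizon"` (the full model horizon) or `"trial"` (through
#'   month 22).
#' @param state_econ,program_pp,annual_rate Optional overrides of the
#'   model's state economics, per-participant program cost (named by arm)
#'   and discount rate, used by the sensitivity analyses.
#' @return A tibble with columns `arm`, `cost`, `qaly_htvas`, `qaly_sf36`.
#' @export
model_outcomes <- function(model, horizon = "horizon", state_econ = NULL,
                           program_pp = NULL, annual_rate = NULL) {
  stopifnot(inherits(model, "cea_model"))
  se <- state_econ %||% model$state_econ
  rate <- annual_rate %||% model$config$annual_rate
  pp <- program_pp %||%
    rlang::set_names(model$program$per_participant, model$program$arm)
  w <- model_windows(model$config, horizon)
  hc <- model$config$half_cycle
  purrr::map_dfr(model$arms, function(a) {
    trace <- model$traces[[a]]
    tibble::tibble(
      arm = a,
      cost = accumulate_costs(trace, se, pp[[a]], rate, w$cost,
                              half_cycle = hc),
      qaly_htvas = accumulate_qalys(trace, se, "htvas", rate, w$qaly,
                                    half_cycle = hc),
      qaly_sf36 = accumulate_qalys(trace, se, "sf36", rate, w$qaly,
                                   half_cycle = hc)
    )
  })
}

#' Pairwise CEA from a fitted model
#'
#' Convenience wrapper: [model_outcomes()] then [cea_compare()].
#'
#' @inheritParams model_outcomes
#' @param wtp Willingness-to-pay threshold (default from the model config).
#' @return A `cea_result`.
#' @export
model_cea <- function(model, horizon = "horizon", state_econ = NULL,
                      program_pp = NULL, annual_rate = NULL, wtp = NULL) {
  per_arm <- model_outcomes(model, horizon, state_econ, program_pp,
                            annual_rate)
  cea_compare(per_arm, wtp = wtp %||% model$config$wtp)
}

#' Generate a synthetic cohort and optionally write it to CSV
#'
#' Thin orchestration wrapper over [simulate_cohort()] / [write_cohort()].
#'
#' @param config A [cohort_config()].
#' @param path Optional output CSV path.
#' @return The cohort tibble (invisibly when `path` is given).
#' @export
synthesize_cohort <- function(config = cohort_config(), path = NULL) {
  cohort <- simulate_cohort(config)
  if (!is.null(path)) {
    write_cohort(cohort, path)
    message(sprintf("wrote %d records (seed %d) to %s",
                    nrow(cohort), config$seed, path))
    return(invisible(cohort))
  }
  cohort
}

#' Run the full analysis and write its reports
#'
#' End-to-end orchestration: validates the inputs, fits the cohort model,
#' computes the end-of-trial and full-horizon comparisons, and writes
#' `transitions.csv` (all estimated segment matrices plus the
#' mortality-adjusted extrapolation matrix), `trace.csv` (both arms'
#' occupancy traces with expected counts) and `cea_result.json` to the
#' output directory. All computation happens before any file is written, so
#' a validation failure leaves the output directory untouched.
#'
#' @param cohort A cohort tibble or path to a cohort CSV.
#' @param out_dir Output directory (created if absent).
#' @inheritParams build_cea_model
#' @return Invisibly, a list with the fitted `model` and the `trial` and
#'   `horizon` `cea_result`s.
#' @export
run_full_analysis <- function(cohort, out_dir,
                              program_costs = default_program_costs(),
                              state_econ = default_state_economics(),
                              config = run_config()) {
  model <- build_cea_model(cohort, program_costs, state_econ, config)
  results <- list(
    trial = model_cea(model, horizon = "trial"),
    horizon = model_cea(model, horizon = "horizon")
  )

  trans <- dplyr::bind_rows(
    tidy_transitions(model$matrices),
    purrr::imap_dfr(model$extrapolation, function(m, a) {
      tidy_transitions(m, arm = a, from_month = 22, to_month = 28)
    })
  )
  traces <- purrr::imap_dfr(model$traces, function(tr, a) {
    dplyr::mutate(tibble::as_tibble(tr), arm = a, .before = 1)
  })
  payload <- list(
    wtp = model$config$wtp,
    discount_annual_rate = model$config$annual_rate,
    horizon_months = model$config$horizon_months,
    results = purrr::map(results, cea_result_payload)
  )

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(trans, file.path(out_dir, "transitions.csv"))
  readr::write_csv(traces, file.path(out_dir, "trace.csv"))
  jsonlite::write_json(payload, file.path(out_dir, "cea_result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(list(model = model), results))
}

cea_result_payload <- function(res) {
  list(
    per_arm = res$per_arm,
    incremental_cost = res$d_cost,
    measures = purrr::map(res$per_measure, function(pm) {
      list(
        incremental_qaly = pm$d_qaly,
        icer = if (pm$label == "ratio") pm$icer else pm$label,
        incremental_nmb = pm$inmb,
        cost_effective = pm$cost_effective
      )
    }),
    wtp = res$wtp
  )
}

#' Run and report the probabilistic sensitivity analysis
#'
#' Wraps [run_psa()] and writes `psa_points.csv` (one row per replication,
#' cost-effectiveness-plane ready).
#'
#' @param model A `cea_model`.
#' @param out_dir Output directory.
#' @param ... Passed to [run_psa()] (`n_reps`, `seed`, `wtp`, spec
#'   overrides).
#' @return The `psa_result`, invisibly.
#' @export
run_psa_analysis <- function(model, out_dir, ...) {
  psa <- run_psa(model, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::as_tibble(psa), file.path(out_dir, "psa_points.csv"))
  invisible(psa)
}

#' Run and report the one-way sensitivity analysis
#'
#' Wraps [run_owsa()] and writes `owsa.csv` (tornado-ready).
#'
#' @param model A `cea_model`.
#' @param out_dir Output directory.
#' @param ... Passed to [run_owsa()].
#' @return The `owsa_result`, invisibly.
#' @export
run_owsa_analysis <- function(model, out_dir, ...) {
  owsa <- run_owsa(model, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::as_tibble(owsa), file.path(out_dir, "owsa.csv"))
  invisible(owsa)
}
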