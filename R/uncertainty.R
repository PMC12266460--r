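#' Truncated-normal parameter specification
#'
#' A normal distribution with mass renormalized over `[lower, upper]`
#' (default the 0--100 survey-score range). `sd = 0` is the degenerate point
#' mass at the (clamped) mean.
#'
#' @param mean,sd Location and scale of the untruncated normal; `sd >= 0`.
#' @param lower,upper Truncation bounds.
#' @export
trunc_normal_spec <- function(mean, sd, lower = 0, upper = 100) {
  if (sd < 0) rlang::abort("sd must be non-negative")
  if (lower >= upper) rlang::abort("lower must be below upper")
  structure(list(mean = mean, sd = sd, lower = lower, upper = upper),
            class = "trunc_normal_spec")
}

#' Draw from a truncated normal by inverse-CDF
#'
#' Vectorised over `mean` and `sd` (recycled to `n`); exactly one uniform
#' draw per sample, so the RNG stream does not depend on the parameters.
#'
#' @param n Number of draws.
#' @param mean,sd Normal parameters (vectors recycled to length `n`).
#' @param lower,upper Truncation bounds.
#' @export
rtrunc_normal <- function(n, mean, sd, lower = 0, upper = 100) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  u <- stats::runif(n)
  out <- pmin(pmax(mean, lower), upper) # sd == 0: point mass
  pos <- sd > 0
  if (any(pos)) {
    plo <- stats::pnorm(lower, mean[pos], sd[pos])
    phi <- stats::pnorm(upper, mean[pos], sd[pos])
    out[pos] <- stats::qnorm(plo + u[pos] * (phi - plo), mean[pos], sd[pos])
  }
  out
}

#' @rdname trunc_normal_spec
#' @param spec A `trunc_normal_spec`.
#' @param n Number of draws.
#' @export
rtrunc_normal_spec <- function(n, spec) {
  rtrunc_normal(n, spec$mean, spec$sd, spec$lower, spec$upper)
}

#' Maximum-likelihood fit of a truncated normal
#'
#' Fits the location and scale of a normal truncated to `[lower, upper]` by
#' direct likelihood maximisation (Nelder--Mead on (mean, log sd),
#' moment-based start, relative log-likelihood tolerance 1e-8). Identical
#' samples yield the degenerate point-mass spec (`sd = 0`).
#'
#' @param x Samples, all within `[lower, upper]`.
#' @param lower,upper Truncation bounds (default 0 and 100).
#' @return A [trunc_normal_spec()].
#' @export
fit_trunc_normal <- function(x, lower = 0, upper = 100) {
  if (length(x) < 2) rlang::abort("need at least 2 samples")
  if (any(x < lower | x > upper)) {
    rlang::abort(sprintf("samples must lie within [%g, %g]", lower, upper))
  }
  if (stats::sd(x) == 0) {
    return(trunc_normal_spec(x[1], 0, lower, upper))
  }
  nll <- function(par) {
    mu <- par[1]
    sigma <- exp(par[2])
    z <- stats::pnorm(upper, mu, sigma) - stats::pnorm(lower, mu, sigma)
    if (z <= 0) return(1e10)
    -sum(stats::dnorm(x, mu, sigma, log = TRUE)) + length(x) * log(z)
  }
  fit <- stats::optim(c(mean(x), log(stats::sd(x))), nll,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 2000))
  trunc_normal_spec(fit$par[1], exp(fit$par[2]), lower, upper)
}

#' Zero-inflated gamma specification
#'
#' A point mass at zero with probability `p_zero`, else a gamma with the
#' given shape and scale; the overall mean is
#' `(1 - p_zero) * shape * scale`. A degenerate positive part (a point mass,
#' e.g. from a zero coefficient of variation) is encoded as `shape = Inf`
#' with `pos_mean` carrying the point.
#'
#' @param p_zero Probability of a zero.
#' @param shape,scale Gamma parameters of the positive part.
#' @param pos_mean Mean of the positive part (defaults to `shape * scale`).
#' @export
zi_gamma_spec <- function(p_zero, shape, scale, pos_mean = shape * scale) {
  if (p_zero < 0 || p_zero > 1) rlang::abort("p_zero must lie in [0, 1]")
  if (is.finite(shape) && (shape <= 0 || scale <= 0)) {
    rlang::abort("shape and scale must be positive")
  }
  structure(
    list(p_zero = p_zero, shape = shape, scale = scale, pos_mean = pos_mean,
         mean = (1 - p_zero) * pos_mean),
    class = "zi_gamma_spec"
  )
}

#' Build a zero-inflated gamma spec from an overall mean
#'
#' Chooses the positive-part mean so the overall mean (zeros included)
#' equals `mean`: positive mean `mean / (1 - p_zero)`, gamma shape
#' `1 / cv^2`, scale `pos_mean * cv^2`. `cv = 0` gives a point mass at the
#' positive mean.
#'
#' @param mean Target overall mean (non-negative).
#' @param p_zero Zero-inflation probability in \[0, 1).
#' @param cv Coefficient of variation of the positive part.
#' @export
zi_gamma_from_mean <- function(mean, p_zero = 0.2, cv = 1.0) {
  if (mean < 0) rlang::abort("mean must be non-negative")
  pos_mean <- if (p_zero < 1) mean / (1 - p_zero) else 0
  if (cv <= 0 || pos_mean == 0) {
    return(zi_gamma_spec(p_zero, Inf, 0, pos_mean = pos_mean))
  }
  shape <- 1 / cv^2
  zi_gamma_spec(p_zero, shape, pos_mean / shape)
}

#' Draw from a zero-inflated gamma spec
#'
#' @param n Number of draws.
#' @param spec A [zi_gamma_spec()].
#' @export
rzi_gamma <- function(n, spec) {
  pos <- if (is.finite(spec$shape)) {
    stats::rgamma(n, shape = spec$shape, scale = spec$scale)
  } else {
    rep(spec$pos_mean, n)
  }
  ifelse(stats::runif(n) < spec$p_zero, 0, pos)
}

#' Fit a zero-inflated gamma to non-negative cost samples
#'
#' The zero probability is the exact fraction of zeros; the gamma shape and
#' scale are maximum-likelihood on the positive part (via
#' [fitdistrplus::fitdist()], moment-based start). All-zero samples return
#' the flagged degenerate spec (`p_zero = 1`); a degenerate positive part
#' (fewer than two distinct positive values) falls back to its point mass.
#'
#' @param x Non-negative samples, at least 2.
#' @return A [zi_gamma_spec()].
#' @export
fit_zi_gamma <- function(x) {
  if (length(x) < 2) rlang::abort("need at least 2 samples")
  if (any(x < 0)) rlang::abort("samples must be non-negative")
  p_zero <- mean(x == 0)
  pos <- x[x > 0]
  if (length(pos) == 0) {
    return(zi_gamma_spec(1, Inf, 0, pos_mean = 0))
  }
  if (length(pos) < 2 || stats::sd(pos) == 0) {
    return(zi_gamma_spec(p_zero, Inf, 0, pos_mean = mean(pos)))
  }
  m <- mean(pos)
  v <- stats::var(pos)
  fit <- fitdistrplus::fitdist(
    pos, "gamma",
    start = list(shape = m^2 / v, rate = m / v)
  )
  shape <- unname(fit$estimate["shape"])
  zi_gamma_spec(p_zero, shape, 1 / unname(fit$estimate["rate"]))
}

#' Default probabilistic-sensitivity-analysis parameter specs
#'
#' One truncated-normal spec per (alive state, QALY measure) centred at the
#' base-case score mean with a standard-error-scale SD
#' (`utility_sd / sqrt(n_per_state)`), and one zero-inflated-gamma spec per
#' (alive state, cost component) whose overall mean equals the base-case
#' monthly cost.
#'
#' @param state_econ Base-case state-economics table.
#' @param utility_sd Individual-level score SD (points).
#' @param n_per_state Effective per-state sample size behind each score mean.
#' @param cost_zero_prob,cost_cv Zero-inflation and positive-part CV of the
#'   cost distributions.
#' @return A list with `utility` (state x measure list of
#'   [trunc_normal_spec()]) and `cost` (state x component list of
#'   [zi_gamma_spec()]).
#' @export
psa_specs <- function(state_econ, utility_sd = 18, n_per_state = 100,
                      cost_zero_prob = 0.2, cost_cv = 1.0) {
  se <- validate_state_economics(state_econ)
  se_scale <- utility_sd / sqrt(n_per_state)
  utility <- purrr::map(rlang::set_names(c("htvas", "sf36")), function(m) {
    purrr::map(rlang::set_names(alive_states), function(s) {
      trunc_normal_spec(se[[m]][se$state == s], se_scale)
    })
  })
  cost <- purrr::map(rlang::set_names(c("rx_monthly", "other_monthly")),
                     function(cmp) {
    purrr::map(rlang::set_names(alive_states), function(s) {
      zi_gamma_from_mean(se[[cmp]][se$state == s], cost_zero_prob, cost_cv)
    })
  })
  list(utility = utility, cost = cost)
}

# sample one state-economics table from PSA specs (shared across arms)
sample_state_economics <- function(specs) {
  tibble::tibble(
    state = alive_states,
    htvas = purrr::map_dbl(specs$utility$htvas[alive_states],
                           \(s) rtrunc_normal_spec(1, s)),
    sf36 = purrr::map_dbl(specs$utility$sf36[alive_states],
                          \(s) rtrunc_normal_spec(1, s)),
    rx_monthly = purrr::map_dbl(specs$cost$rx_monthly[alive_states],
                                \(s) rzi_gamma(1, s)),
    other_monthly = purrr::map_dbl(specs$cost$other_monthly[alive_states],
                                   \(s) rzi_gamma(1, s))
  )
}

#' Probabilistic sensitivity analysis over the fitted cohort model
#'
#' Per replication, resamples the state-conditional survey-score means
#' (truncated normal) and monthly cost means (zero-inflated gamma) -- shared
#' by both arms, so incremental effects are driven by occupancy differences
#' -- reruns the economic accumulation and the pairwise comparison, and
#' records the incremental cost, incremental QALYs, ICER and the
#' cost-effectiveness decision at the threshold. Transition probabilities
#' are not resampled. Deterministic given `seed`.
#'
#' @param model A `cea_model` from [build_cea_model()].
#' @param n_reps Number of replications (default 1000).
#' @param seed Integer seed.
#' @param wtp Willingness-to-pay threshold (default from the model config).
#' @param specs Parameter specs as from [psa_specs()]; default built from
#'   the model's base-case state economics with [psa_specs()] defaults.
#' @param ... Passed to [psa_specs()] when `specs` is `NULL` (e.g.
#'   `utility_sd`, `cost_zero_prob`, `cost_cv`).
#' @return A `psa_result`: a tibble with one row per replication (columns
#'   `rep`, `d_cost`, `d_qaly_htvas`, `d_qaly_sf36`, `icer_htvas`,
#'   `icer_sf36`, `cost_effective_htvas`, `cost_effective_sf36`) carrying
#'   `fraction_cost_effective` (named per measure) and `wtp` attributes.
#' @export
run_psa <- function(model, n_reps = 1000, seed = 1L, wtp = NULL,
                    specs = NULL, ...) {
  stopifnot(inherits(model, "cea_model"))
  if (n_reps < 1) rlang::abort("n_reps must be positive")
  wtp <- wtp %||% model$config$wtp
  specs <- specs %||% psa_specs(model$state_econ, ...)
  set.seed(seed)
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    se_r <- sample_state_economics(specs)
    res <- model_cea(model, state_econ = se_r, wtp = wtp)
    td <- tidy(res)
    tibble::tibble(
      rep = r,
      d_cost = res$d_cost,
      d_qaly_htvas = td$d_qaly[td$measure == "htvas"],
      d_qaly_sf36 = td$d_qaly[td$measure == "sf36"],
      icer_htvas = td$icer[td$measure == "htvas"],
      icer_sf36 = td$icer[td$measure == "sf36"],
      cost_effective_htvas = td$cost_effective[td$measure == "htvas"],
      cost_effective_sf36 = td$cost_effective[td$measure == "sf36"]
    )
  })
  structure(reps,
    fraction_cost_effective = c(
      htvas = mean(reps$cost_effective_htvas),
      sf36 = mean(reps$cost_effective_sf36)
    ),
    wtp = wtp, seed = seed,
    class = c("psa_result", class(reps))
  )
}

#' @export
print.psa_result <- function(x, ...) {
  f <- attr(x, "fraction_cost_effective")
  cat(sprintf(
    "<PSA: %d replications, WTP $%s/QALY; cost-effective %.1f%% (HT-VAS), %.1f%% (SF-36)>\n",
    nrow(x), format(attr(x, "wtp"), big.mark = ","),
    100 * f[["htvas"]], 100 * f[["sf36"]]
  ))
  NextMethod()
}

#' Glance at a PSA result
#' @param x A `psa_result`.
#' @param ... Unused.
#' @method glance psa_result
#' @export
glance.psa_result <- function(x, ...) {
  f <- attr(x, "fraction_cost_effective")
  tibble::tibble(
    n_reps = nrow(x), wtp = attr(x, "wtp"),
    fraction_cost_effective_htvas = f[["htvas"]],
    fraction_cost_effective_sf36 = f[["sf36"]],
    mean_d_cost = mean(x$d_cost),
    mean_d_qaly_htvas = mean(x$d_qaly_htvas),
    mean_d_qaly_sf36 = mean(x$d_qaly_sf36)
  )
}

#' One-way deterministic sensitivity analysis
#'
#' Reruns the fitted pipeline once per scenario: each arm's phase-2 program
#' delivery cost multiplied by the given factors (one scenario per arm and
#' direction), all state-conditional monthly medication costs scaled
#' together, all other-healthcare costs scaled together, and the discount
#' rate replaced by each alternative. The base case is recomputed internally
#' and included as the first row.
#'
#' @param model A `cea_model`.
#' @param multipliers Low/high multipliers (default `c(0.8, 1.2)`).
#' @param discount_alts Alternative annual discount rates (default 1% and
#'   5%).
#' @param wtp Willingness-to-pay threshold (default from the model config).
#' @return An `owsa_result` tibble: `parameter`, `direction`, `new_value`
#'   (the perturbed per-participant phase-2 cost or discount rate; `NA` for
#'   multi-state cost scenarios), `d_cost`, `d_qaly_htvas`, `d_qaly_sf36`,
#'   `icer_htvas`, `icer_sf36`.
#' @export
run_owsa <- function(model, multipliers = c(0.8, 1.2),
                     discount_alts = c(0.01, 0.05), wtp = NULL) {
  stopifnot(inherits(model, "cea_model"))
  wtp <- wtp %||% model$config$wtp
  row_of <- function(parameter, direction, new_value, res) {
    td <- tidy(res)
    tibble::tibble(
      parameter = parameter, direction = direction, new_value = new_value,
      d_cost = res$d_cost,
      d_qaly_htvas = td$d_qaly[td$measure == "htvas"],
      d_qaly_sf36 = td$d_qaly[td$measure == "sf36"],
      icer_htvas = td$icer[td$measure == "htvas"],
      icer_sf36 = td$icer[td$measure == "sf36"]
    )
  }
  dir_label <- function(m) if (m > 1) "high" else "low"

  rows <- list(row_of("base_case", "base", NA_real_,
                      model_cea(model, wtp = wtp)))
  prog <- model$program
  for (arm in prog$arm) {
    for (m in multipliers) {
      pp2 <- round_cents(prog$phase2_per_participant[prog$arm == arm] * m)
      pp_override <- rlang::set_names(prog$per_participant, prog$arm)
      pp_override[arm] <- prog$phase1_per_participant[prog$arm == arm] + pp2
      res <- model_cea(model, program_pp = pp_override, wtp = wtp)
      rows <- c(rows, list(row_of(
        paste0("program_cost_phase2_", arm), dir_label(m), pp2, res
      )))
    }
  }
  for (cmp in c("rx_monthly", "other_monthly")) {
    for (m in multipliers) {
      se <- model$state_econ
      se[[cmp]] <- se[[cmp]] * m
      res <- model_cea(model, state_econ = se, wtp = wtp)
      rows <- c(rows, list(row_of(cmp, dir_label(m), NA_real_, res)))
    }
  }
  for (r in discount_alts) {
    res <- model_cea(model, annual_rate = r, wtp = wtp)
    rows <- c(rows, list(row_of("discount_rate",
                                if (r > model$config$annual_rate) "high" else "low",
                                r, res)))
  }
  out <- dplyr::bind_rows(rows)
  structure(out, wtp = wtp, class = c("owsa_result", class(out)))
}
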