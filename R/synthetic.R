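#' Configuration for the synthetic trial-cohort generator
#'
#' Collects the statistical targets the generator emulates: arm sizes,
#' baseline demographics, the observed end-of-phase state occupancies, the
#' state-conditional survey-score means and monthly out-of-pocket cost means,
#' and nuisance parameters (score SD, cost zero-inflation and coefficient of
#' variation, missingness rate). Defaults reproduce the published trial:
#' arms of 153 (education control) and 149 (individual coaching), baseline
#' weight 99.8 (SD 14.6) kg, age 55.4 (SD 10.3), 82.7% female, and the
#' packaged month-16/22 occupancy and state-economics tables.
#'
#' @param n_per_arm Named integer vector of arm sizes.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param baseline_weight_mean_kg,baseline_weight_sd_kg Baseline weight
#'   distribution (kg), truncated to plausible adult weights.
#' @param age_mean,age_sd Age distribution (years), truncated to the trial's
#'   21--75 eligibility window.
#' @param female_fraction Probability a participant is female.
#' @param month4_occupancy Probability vector over the three alive states at
#'   the end of the active weight-loss phase (month 4), identical across arms
#'   (both arms receive the same phase-1 program).
#' @param target_occupancy Tibble as [default_occupancy_targets()]: per
#'   (arm, month in 16/22), the occupancy over the alive states.
#' @param state_econ State-conditional survey-score and monthly-cost means,
#'   as [default_state_economics()].
#' @param utility_sd SD of the truncated-normal survey-score draws (score
#'   points, 0--100 scale).
#' @param cost_zero_prob Probability a monthly cost is exactly zero.
#' @param cost_cv Coefficient of variation of the positive (gamma) cost
#'   component; the state-conditional overall mean (zeros included) equals
#'   the configured mean.
#' @param missing_rate Missing-completely-at-random rate applied to survey
#'   scores and self-reported costs.
#' @param max_loss_fraction Truncation of the open top weight-loss category
#'   (default 25% loss).
#' @param stay_weight Diagonal weight of the iterative-proportional-fitting
#'   prior coupling consecutive assessment occupancies (larger = stickier
#'   trajectories).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_arm = c(education_control = 153L,
                                        individual_coaching = 149L),
                          seed = 1L,
                          baseline_weight_mean_kg = 99.8,
                          baseline_weight_sd_kg = 14.6,
                          age_mean = 55.4, age_sd = 10.3,
                          female_fraction = 0.827,
                          month4_occupancy = c(lt5 = 0.30, m5_10 = 0.30,
                                               gt10 = 0.40),
                          target_occupancy = default_occupancy_targets(),
                          state_econ = default_state_economics(),
                          utility_sd = 18,
                          cost_zero_prob = 0.2,
                          cost_cv = 1.0,
                          missing_rate = 0.05,
                          max_loss_fraction = 0.25,
                          stay_weight = 4) {
  if (any(n_per_arm <= 0) || is.null(names(n_per_arm))) {
    rlang::abort("n_per_arm must be a named vector of positive arm sizes")
  }
  check_simplex(month4_occupancy, "month4_occupancy")
  for (r in seq_len(nrow(target_occupancy))) {
    check_simplex(
      unlist(target_occupancy[r, alive_states]),
      sprintf("target_occupancy row %d (%s, month %s)", r,
              target_occupancy$arm[r], target_occupancy$month[r])
    )
  }
  state_econ <- validate_state_economics(state_econ)
  for (m in c("htvas", "sf36")) {
    if (any(diff(state_econ[[m]]) <= 0)) {
      rlang::abort(sprintf(
        "%s means must increase strictly with the weight-loss category", m
      ))
    }
  }
  if (female_fraction < 0 || female_fraction > 1) {
    rlang::abort("female_fraction must lie in [0, 1]")
  }
  if (cost_zero_prob < 0 || cost_zero_prob >= 1) {
    rlang::abort("cost_zero_prob must lie in [0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    rlang::abort("missing_rate must lie in [0, 1)")
  }
  if (utility_sd < 0 || cost_cv < 0) {
    rlang::abort("utility_sd and cost_cv must be non-negative")
  }
  structure(
    list(
      n_per_arm = n_per_arm, seed = as.integer(seed),
      baseline_weight_mean_kg = baseline_weight_mean_kg,
      baseline_weight_sd_kg = baseline_weight_sd_kg,
      age_mean = age_mean, age_sd = age_sd,
      female_fraction = female_fraction,
      month4_occupancy = month4_occupancy,
      target_occupancy = target_occupancy,
      state_econ = state_econ,
      utility_sd = utility_sd, cost_zero_prob = cost_zero_prob,
      cost_cv = cost_cv, missing_rate = missing_rate,
      max_loss_fraction = max_loss_fraction, stay_weight = stay_weight
    ),
    class = "cohort_config"
  )
}

check_simplex <- function(p, what, tol = 1e-9) {
  if (any(p < 0) || abs(sum(p) - 1) > tol) {
    rlang::abort(sprintf(
      "%s must be a probability vector summing to 1 (got sum %.12f)",
      what, sum(p)
    ))
  }
}

# IPF coupling of two occupancy marginals over the alive states: fits a 3x3
# joint with row marginal p and column marginal q, starting from a
# diagonal-favouring prior so trajectories tend to stay in their category.
# Returns the conditional transition kernel K[i, j] = P(next = j | now = i);
# rows with zero marginal mass get a self-loop.
ipf_coupling <- function(p, q, stay_weight = 4, tol = 1e-12, max_iter = 2000) {
  k <- length(p)
  stopifnot(length(q) == k)
  joint <- matrix(1, k, k)
  diag(joint) <- stay_weight
  joint[p == 0, ] <- 0
  joint[, q == 0] <- 0
  for (it in seq_len(max_iter)) {
    rs <- rowSums(joint)
    joint <- joint * ifelse(rs > 0, p / rs, 0)
    cs <- colSums(joint)
    joint <- sweep(joint, 2, ifelse(cs > 0, q / cs, 0), "*")
    if (max(abs(rowSums(joint) - p)) < tol) break
  }
  cond <- joint / ifelse(rowSums(joint) > 0, rowSums(joint), 1)
  for (i in seq_len(k)) if (sum(cond[i, ]) == 0) cond[i, i] <- 1
  dimnames(cond) <- list(names(p), names(p))
  cond
}

# uniform percent-loss draw within a category's interval; boundaries nudged
# so re-categorization always recovers the drawn category
draw_loss <- function(states, max_loss) {
  n <- length(states)
  l <- numeric(n)
  i <- states == "lt5"
  l[i] <- pmin(stats::runif(sum(i), -0.05, 0.05), 0.05 - 1e-9)
  i <- states == "m5_10"
  l[i] <- stats::runif(sum(i), 0.05, 0.10)
  i <- states == "gt10"
  l[i] <- pmax(stats::runif(sum(i), 0.10, max_loss), 0.10 + 1e-9)
  l
}

# zero-inflated gamma monthly-cost draw with a target overall mean (zeros
# included) and positive-part coefficient of variation
draw_cost <- function(n, mean, p_zero, cv) {
  pos_mean <- if (p_zero < 1) mean / (1 - p_zero) else 0
  x <- if (cv <= 0) {
    rep(pos_mean, n)
  } else {
    shape <- 1 / cv^2
    stats::rgamma(n, shape = shape, scale = pos_mean / shape)
  }
  ifelse(stats::runif(n) < p_zero, 0, x)
}

#' Columns of the cohort CSV layout
#' @export
cohort_columns <- c(
  "participant_id", "arm", "sex", "age_years",
  "weight_m0", "weight_m4", "weight_m16", "weight_m22",
  "htvas_m0", "htvas_m16", "htvas_m22",
  "sf36_m0", "sf36_m16", "sf36_m22",
  "rx_cost_monthly", "other_cost_monthly"
)

#' Generate a synthetic trial cohort
#'
#' Draws participant-level longitudinal records with the statistical
#' structure the downstream analysis assumes. Per arm, each participant gets
#' a month-4 weight-loss category from the end-of-phase-1 occupancy, then
#' month-16 and month-22 categories from iterative-proportional-fitting
#' couplings of the configured marginal occupancies (so empirical
#' occupancies converge to the targets as n grows); weights at months
#' 4/16/22 are back-computed from baseline weight and a uniform percent loss
#' within the drawn category (the open top category truncated at
#' `max_loss_fraction`); survey scores are truncated-normal around the
#' state-conditional means; monthly costs are zero-inflated gamma around the
#' month-16-state-conditional means; survey and cost fields are then blanked
#' missing-completely-at-random.
#'
#' @param config A [cohort_config()].
#' @return A tibble with [cohort_columns], one row per participant;
#'   deterministic given `config$seed`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  se <- config$state_econ
  u_mean <- list(htvas = rlang::set_names(se$htvas, se$state),
                 sf36 = rlang::set_names(se$sf36, se$state))
  c_mean <- list(rx = rlang::set_names(se$rx_monthly, se$state),
                 other = rlang::set_names(se$other_monthly, se$state))

  arms <- names(config$n_per_arm)
  rows <- purrr::map(arms, function(arm) {
    n <- config$n_per_arm[[arm]]
    tgt <- config$target_occupancy
    q16 <- occupancy_row(tgt, arm, 16)
    q22 <- occupancy_row(tgt, arm, 22)
    q4 <- config$month4_occupancy
    k_4_16 <- ipf_coupling(q4, q16, config$stay_weight)
    k_16_22 <- ipf_coupling(q16, q22, config$stay_weight)

    sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
    age <- rtrunc_normal(n, config$age_mean, config$age_sd, 21, 75)
    w0 <- rtrunc_normal(n, config$baseline_weight_mean_kg,
                        config$baseline_weight_sd_kg, 55, 180)

    s4 <- sample(alive_states, n, replace = TRUE, prob = q4)
    s16 <- vapply(s4, function(s) {
      sample(alive_states, 1, prob = k_4_16[s, ])
    }, character(1))
    s22 <- vapply(s16, function(s) {
      sample(alive_states, 1, prob = k_16_22[s, ])
    }, character(1))

    w4 <- w0 * (1 - draw_loss(s4, config$max_loss_fraction))
    w16 <- w0 * (1 - draw_loss(s16, config$max_loss_fraction))
    w22 <- w0 * (1 - draw_loss(s22, config$max_loss_fraction))

    score <- function(measure, states) {
      rtrunc_normal(n, u_mean[[measure]][states], config$utility_sd, 0, 100)
    }
    out <- tibble::tibble(
      participant_id = sprintf("%s_%04d", substr(arm, 1, 2), seq_len(n)),
      arm = arm, sex = sex, age_years = age,
      weight_m0 = w0, weight_m4 = w4, weight_m16 = w16, weight_m22 = w22,
      htvas_m0 = score("htvas", rep("lt5", n)),
      htvas_m16 = score("htvas", s16),
      htvas_m22 = score("htvas", s22),
      sf36_m0 = score("sf36", rep("lt5", n)),
      sf36_m16 = score("sf36", s16),
      sf36_m22 = score("sf36", s22),
      rx_cost_monthly = draw_cost(n, c_mean$rx[s16], config$cost_zero_prob,
                                  config$cost_cv),
      other_cost_monthly = draw_cost(n, c_mean$other[s16],
                                     config$cost_zero_prob, config$cost_cv)
    )
    if (config$missing_rate > 0) {
      blank <- c("htvas_m0", "htvas_m16", "htvas_m22",
                 "sf36_m0", "sf36_m16", "sf36_m22",
                 "rx_cost_monthly", "other_cost_monthly")
      for (col in blank) {
        out[[col]][stats::runif(n) < config$missing_rate] <- NA_real_
      }
    }
    out
  })
  dplyr::bind_rows(rows)
}

occupancy_row <- function(target_occupancy, arm, month) {
  r <- target_occupancy[target_occupancy$arm == arm &
                          target_occupancy$month == month, ]
  if (nrow(r) != 1L) {
    rlang::abort(sprintf(
      "target_occupancy has no row for arm '%s', month %s", arm, month
    ))
  }
  rlang::set_names(as.numeric(r[, alive_states]), alive_states)
}
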