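test_that("per-participant program costs divide and round to the cent", {
  expect_equal(per_participant_cost(82741.19, 149), 555.31)
  expect_equal(per_participant_cost(4085.13, 153), 26.70)
  expect_equal(per_participant_cost(0, 10), 0)
  expect_error(per_participant_cost(100, 0), "positive")
})

test_that("the packaged delivery-cost ledger reproduces the published totals", {
  pc <- summarize_program_costs(default_program_costs())
  ec <- pc[pc$arm == "education_control", ]
  ic <- pc[pc$arm == "individual_coaching", ]
  expect_equal(ec$phase1_per_participant, 325.12)
  expect_equal(ic$phase1_per_participant, 325.12)
  expect_equal(ec$phase2_per_participant, 26.70)
  expect_equal(ic$phase2_per_participant, 555.31)
  expect_equal(ec$per_participant, 351.82)
  expect_equal(ic$per_participant, 880.43)
  expect_equal(ic$per_participant - ec$per_participant, 528.61)
  expect_equal(ic$phase2_total, 82741.19)
})

test_that("discount factors follow the annual compounding convention", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(12, 0.03), 1 / 1.03)
  expect_equal(discount_factor(60, 0.03), 1.03^-5)
  expect_equal(discount_factor(60, 0.03, time_zero_month = 60), 1)
  expect_equal(discount_factor(24, 0), 1)
  expect_error(discount_factor(-1, 0.03), "precede")
  expect_error(discount_factor(12, 1.5), "\\[0, 1\\)")
})

test_that("state monthly costs sum medication and other components", {
  se <- default_state_economics()
  expect_equal(monthly_state_cost(se, "m5_10"), 74.40)
  expect_equal(monthly_state_cost(se, "gt10"), 79.01)
  expect_equal(monthly_state_cost(se, "lt5"), 102.34)
  expect_equal(monthly_state_cost(se, "dead"), 0)
  zero <- se
  zero$rx_monthly <- 0
  zero$other_monthly <- 0
  expect_equal(monthly_state_cost(zero, "gt10"), 0)
  expect_error(monthly_state_cost(se, "obese"), "unknown state")
})

test_that("cost accumulation adds undiscounted program costs to discounted OOP", {
  se <- default_state_economics()
  zero_se <- dplyr::mutate(se, rx_monthly = 0, other_monthly = 0)
  tr <- make_trace(c(0, 4, 16, 22), rep(c(1, 0, 0, 0), 4))
  # zero state costs: the trial-window total is the program cost alone
  expect_equal(
    accumulate_costs(tr, zero_se, 880.43, 0.03, window = c(0, 22)),
    880.43
  )
  # undiscounted constant occupancy: 12 months x $102.34
  tr12 <- make_trace(c(0, 6, 12), rep(c(1, 0, 0, 0), 3))
  expect_equal(
    accumulate_costs(tr12, se, 0, 0, window = c(0, 12)),
    12 * 102.34
  )
  # all-dead occupancy: program costs only
  dead_tr <- make_trace(c(0, 6, 12), rep(c(0, 0, 0, 1), 3))
  expect_equal(accumulate_costs(dead_tr, se, 351.82, 0.03, c(0, 12)), 351.82)
})

test_that("discounting shrinks totals by a bounded factor", {
  se <- default_state_economics()
  set.seed(55)
  sched <- transition_schedule(list(random_tm()), random_tm())
  tr <- run_markov(c(1, 0, 0, 0), sched, horizon_months = 48)
  undisc <- accumulate_costs(tr, se, 0, 0, window = c(0, 48))
  disc <- accumulate_costs(tr, se, 0, 0.03, window = c(0, 48))
  expect_lte(disc, undisc)
  expect_gte(disc, undisc * 1.03^-4)
})

test_that("QALY accumulation is anchored, linear and bounded", {
  perfect <- dplyr::mutate(default_state_economics(),
                           htvas = c(99.98, 99.99, 100))
  tr_gt10 <- make_trace(c(0, 6, 12), rep(c(0, 0, 1, 0), 3))
  expect_equal(accumulate_qalys(tr_gt10, perfect, "htvas", 0, c(0, 12)), 1)

  se <- default_state_economics()
  expect_equal(accumulate_qalys(tr_gt10, se, "htvas", 0, c(0, 12)), 0.8296)
  tr_lt5 <- make_trace(c(0, 6, 12), rep(c(1, 0, 0, 0), 3))
  expect_equal(
    accumulate_qalys(tr_gt10, se, "htvas", 0, c(0, 12)) -
      accumulate_qalys(tr_lt5, se, "htvas", 0, c(0, 12)),
    (82.96 - 64.71) / 100
  )
  # superposition in the occupancy argument
  mix <- make_trace(c(0, 6, 12), rep(c(0.4, 0, 0.6, 0), 3))
  expect_equal(
    accumulate_qalys(mix, se, "sf36", 0.03, c(0, 12)),
    0.4 * accumulate_qalys(tr_lt5, se, "sf36", 0.03, c(0, 12)) +
      0.6 * accumulate_qalys(tr_gt10, se, "sf36", 0.03, c(0, 12))
  )
  # bounded by years in window; dead contributes nothing
  dead_tr <- make_trace(c(0, 6, 12), rep(c(0, 0, 0, 1), 3))
  expect_equal(accumulate_qalys(dead_tr, se, "htvas", 0, c(0, 12)), 0)
  set.seed(66)
  sched <- transition_schedule(list(random_tm()), random_tm())
  tr <- run_markov(c(1, 0, 0, 0), sched, horizon_months = 60)
  expect_lte(accumulate_qalys(tr, se, "htvas", 0, c(0, 60)), 5)
})

test_that("window handling clips intervals and rejects out-of-range windows", {
  se <- default_state_economics()
  tr <- make_trace(c(0, 4, 16, 22), rep(c(1, 0, 0, 0), 4))
  # window months 10-22 spans 12 months of the 4-16 and 16-22 intervals
  expect_equal(accumulate_qalys(tr, se, "htvas", 0, c(10, 22)), 0.6471)
  expect_error(accumulate_costs(tr, se, 0, 0.03, c(0, 60)), "outside the trace")
  expect_error(accumulate_qalys(tr, se, "htvas", 0.03, c(-5, 22)), "outside")
})

test_that("half-cycle attribution averages endpoints and discounts at midpoints", {
  se <- default_state_economics()
  tr <- make_trace(c(0, 12), c(1, 0, 0, 0, 0, 0, 1, 0))
  hc <- accumulate_qalys(tr, se, "htvas", 0, c(0, 12), half_cycle = TRUE)
  expect_equal(hc, (64.71 + 82.96) / 2 / 100)
  cost_hc <- accumulate_costs(tr, se, 0, 0.03, c(0, 12), half_cycle = TRUE)
  expect_equal(cost_hc, 12 * (102.34 + 79.01) / 2 * 1.03^-0.5)
})
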