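test_that("the truncated-normal fitter recovers generating parameters", {
  set.seed(88)
  x <- rtrunc_normal(10000, 80, 15, 0, 100)
  fit <- fit_trunc_normal(x)
  expect_lt(abs(fit$mean - 80), 0.5)
  expect_lt(abs(fit$sd - 15), 0.5)
  # degenerate: constant samples give a point mass
  c_fit <- fit_trunc_normal(rep(73.73, 5))
  expect_equal(c_fit$mean, 73.73)
  expect_equal(c_fit$sd, 0)
  expect_equal(rtrunc_normal_spec(3, c_fit), rep(73.73, 3))
  expect_error(fit_trunc_normal(c(50, 105)), "\\[0, 100\\]")
  expect_error(fit_trunc_normal(70), "at least 2")
})

test_that("truncated-normal draws respect bounds and the degenerate case", {
  set.seed(89)
  x <- rtrunc_normal(5000, 95, 20, 0, 100)
  expect_true(all(x >= 0 & x <= 100))
  expect_gt(mean(x > 90), 0.3) # mass piles near the upper bound
  expect_equal(rtrunc_normal(4, c(30, 120), 0), c(30, 100, 30, 100))
})

test_that("the zero-inflated gamma fitter recovers generating parameters", {
  expect_equal(fit_zi_gamma(c(0, 0, 10, 10))$p_zero, 0.5)
  expect_equal(fit_zi_gamma(c(0, 0, 10, 10))$pos_mean, 10)
  set.seed(90)
  spec <- zi_gamma_spec(0.3, 2, 20)
  x <- rzi_gamma(10000, spec)
  fit <- fit_zi_gamma(x)
  expect_lt(abs(fit$p_zero - 0.3) / 0.3, 0.05)
  expect_lt(abs(fit$shape - 2) / 2, 0.05)
  expect_lt(abs(fit$scale - 20) / 20, 0.05)
  # moment consistency: implied mean tracks the sample mean
  expect_lt(abs(fit$mean - mean(x)) / mean(x), 0.01)
  # all-zero samples give the flagged degenerate spec
  allz <- fit_zi_gamma(c(0, 0, 0))
  expect_equal(allz$p_zero, 1)
  expect_equal(allz$mean, 0)
  expect_error(fit_zi_gamma(c(-1, 2)), "non-negative")
})

test_that("mean-parameterized zero-inflated gamma has the stated moments", {
  spec <- zi_gamma_from_mean(44.97, p_zero = 0.2, cv = 1.0)
  expect_equal(spec$mean, 44.97)
  expect_equal(spec$pos_mean, 44.97 / 0.8)
  expect_equal(spec$shape, 1)
  set.seed(91)
  x <- rzi_gamma(50000, spec)
  expect_lt(abs(mean(x) - 44.97) / 44.97, 0.03)
  # cv = 0 collapses to a two-point distribution
  d <- zi_gamma_from_mean(40, p_zero = 0, cv = 0)
  expect_equal(rzi_gamma(3, d), rep(40, 3))
})

test_that("a zero-variance PSA degenerates to the base case exactly", {
  model <- base_model()
  base <- tidy(model_cea(model))
  psa <- run_psa(model, n_reps = 5, seed = 3,
                 utility_sd = 0, cost_zero_prob = 0, cost_cv = 0)
  expect_equal(unique(psa$d_cost), base$d_cost[1])
  expect_equal(unique(psa$d_qaly_htvas), base$d_qaly[base$measure == "htvas"])
  expect_equal(unique(psa$icer_sf36), base$icer[base$measure == "sf36"])
  expect_true(all(psa$cost_effective_htvas))
})

test_that("the PSA is reproducible given a seed", {
  model <- base_model()
  a <- run_psa(model, n_reps = 40, seed = 14)
  b <- run_psa(model, n_reps = 40, seed = 14)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c2 <- run_psa(model, n_reps = 40, seed = 15)
  expect_false(identical(a$d_cost, c2$d_cost))
  expect_equal(nrow(a), 40)
  f <- attr(a, "fraction_cost_effective")
  expect_true(all(f >= 0 & f <= 1))
})

test_that("one-way scenarios reprice the coaching program by +/-20%", {
  owsa <- run_owsa(base_model())
  ic <- owsa[owsa$parameter == "program_cost_phase2_individual_coaching", ]
  expect_equal(ic$new_value[ic$direction == "high"], 666.37)
  expect_equal(ic$new_value[ic$direction == "low"], 444.25)
  ec <- owsa[owsa$parameter == "program_cost_phase2_education_control", ]
  expect_equal(ec$new_value[ec$direction == "high"], 32.04)
  expect_equal(ec$new_value[ec$direction == "low"], 21.36)
  expect_equal(nrow(owsa), 11) # base + 4 program + 2 rx + 2 other + 2 discount
})

test_that("pure cost scenarios leave incremental QALYs untouched", {
  owsa <- run_owsa(base_model())
  base <- owsa[owsa$direction == "base", ]
  costly <- owsa[owsa$parameter != "discount_rate", ]
  expect_true(all(costly$d_qaly_htvas == base$d_qaly_htvas))
  expect_true(all(costly$d_qaly_sf36 == base$d_qaly_sf36))
  disc <- owsa[owsa$parameter == "discount_rate", ]
  expect_true(all(disc$d_qaly_htvas != base$d_qaly_htvas))
})

test_that("scenario ICERs are self-consistent and monotone in program cost", {
  owsa <- run_owsa(base_model())
  ok <- owsa$d_cost > 0 & owsa$d_qaly_htvas > 0
  expect_equal(owsa$icer_htvas[ok] * owsa$d_qaly_htvas[ok], owsa$d_cost[ok])
  base_icer <- owsa$icer_htvas[owsa$direction == "base"]
  ic <- owsa[owsa$parameter == "program_cost_phase2_individual_coaching", ]
  expect_gt(ic$icer_htvas[ic$direction == "high"], base_icer)
  expect_lt(ic$icer_htvas[ic$direction == "low"], base_icer)
})
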