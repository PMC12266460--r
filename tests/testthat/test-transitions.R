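test_that("weight change categorization follows the 5%/10% thresholds", {
  expect_identical(categorize_weight(99.8, 99.8), "lt5")
  expect_identical(categorize_weight(100, 103), "lt5") # weight gain
  expect_identical(categorize_weight(100, 95.0), "m5_10") # 5% exactly
  expect_identical(categorize_weight(100, 90.0), "m5_10") # 10% exactly
  expect_identical(categorize_weight(100, 89.9), "gt10") # 10.1%
  expect_identical(
    categorize_weight(100, c(99, 92, 85, NA)),
    c("lt5", "m5_10", "gt10", NA)
  )
  expect_error(categorize_weight(0, 90), "positive")
  expect_error(categorize_weight(100, -1), "positive")
})

test_that("transition matrices validate stochasticity and the absorbing row", {
  m <- diag(4)
  expect_s3_class(transition_matrix(m, 6), "transition_matrix")
  expect_error(transition_matrix(m * 0.5, 6), "sum to 1")
  expect_error(transition_matrix(m * 2, 6), "\\[0, 1\\]")
  bad <- diag(4)
  bad[4, ] <- c(0.5, 0, 0, 0.5)
  expect_error(transition_matrix(bad, 6), "absorbing")
  expect_error(transition_matrix(diag(3), 6), "4x4")
  expect_error(transition_matrix(m, 0), "positive")
})

test_that("empirical estimation matches observed transition proportions", {
  # 35 participants with >10% loss at month 16, 9 of whom regress to the
  # moderate state by month 22
  co <- toy_cohort(
    w0 = 100, w16 = 88,
    w22 = c(rep(93, 9), rep(88, 26)),
    arm = "education_control"
  )
  m <- suppressWarnings(estimate_transition_matrix(co, 16, 22))
  expect_equal(m["gt10", "m5_10"], 0.2571, tolerance = 1e-3)
  expect_equal(m["gt10", "gt10"], 26 / 35)
  expect_equal(interval_months(m), 6)

  # everyone stays put -> identity
  co2 <- toy_cohort(w0 = 100, w16 = c(99, 93, 88), w22 = c(99, 93, 88))
  m2 <- suppressWarnings(estimate_transition_matrix(co2, 16, 22))
  expect_equal(unclass(m2), diag(4), ignore_attr = TRUE)
})

test_that("estimation is invariant to record order and duplication", {
  co <- toy_cohort(
    w0 = 100, w16 = c(99, 99, 93, 93, 88, 88),
    w22 = c(99, 93, 93, 88, 88, 99)
  )
  m <- estimate_transition_matrix(co, 16, 22)
  shuffled <- co[sample(nrow(co)), ]
  tripled <- dplyr::bind_rows(co, co, co)
  expect_equal(unclass(estimate_transition_matrix(shuffled, 16, 22)),
               unclass(m))
  expect_equal(unclass(estimate_transition_matrix(tripled, 16, 22)),
               unclass(m))
})

test_that("empty origin states get a warned self-loop; no data is an error", {
  co <- toy_cohort(w0 = 100, w16 = 99, w22 = 99) # only lt5 occupied
  expect_warning(
    expect_warning(m <- estimate_transition_matrix(co, 16, 22), "self-loop"),
    "self-loop"
  )
  expect_equal(m["m5_10", "m5_10"], 1)
  expect_equal(m["gt10", "gt10"], 1)
  co$weight_m22 <- NA_real_
  expect_error(estimate_transition_matrix(co, 16, 22), "no records")
})

test_that("estimated matrices recover the generator's coupling at n = 10,000", {
  co <- big_cohort()
  tgt <- default_occupancy_targets()
  for (a in unique(co$arm)) {
    q16 <- unlist(tgt[tgt$arm == a & tgt$month == 16, alive_states])
    q22 <- unlist(tgt[tgt$arm == a & tgt$month == 22, alive_states])
    truth <- weightcea:::ipf_coupling(q16, q22, stay_weight = 4)
    est <- estimate_transition_matrix(co[co$arm == a, ], 16, 22)
    expect_lt(max(abs(unclass(est)[1:3, 1:3] - truth)), 0.02)
  }
})

test_that("annualization is the matrix square and matches path enumeration", {
  expect_equal(unclass(to_annual(transition_matrix(diag(4), 6))),
               diag(4), ignore_attr = TRUE)

  m <- diag(4)
  m[1, ] <- c(0.9, 0, 0, 0.1)
  a <- to_annual(transition_matrix(m, 6))
  expect_equal(a["lt5", "lt5"], 0.81)
  expect_equal(a["lt5", "dead"], 0.19)
  expect_equal(interval_months(a), 12)

  # oracle: brute-force enumeration of all two-step paths
  set.seed(101)
  for (rep in 1:100) {
    m <- random_tm()
    a <- to_annual(m)
    expect_lt(max(abs(rowSums(a) - 1)), 1e-9)
    oracle <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) {
      oracle[i, j] <- sum(sapply(1:4, function(k) m[i, k] * m[k, j]))
    }
    expect_equal(unclass(a), oracle, ignore_attr = TRUE)
  }
})

test_that("probability rescaling is the constant-hazard conversion", {
  expect_equal(rescale_probability(0, 1, 5), 0)
  expect_equal(rescale_probability(0.19, 1, 0.5), 0.1)
  expect_equal(1 - (1 - rescale_probability(0.19, 1, 0.5))^2, 0.19)
  # annual probability consistent with a 4.3% five-year cumulative risk
  p_annual <- rescale_probability(0.043, 5, 1)
  expect_equal(p_annual, 0.00875, tolerance = 1e-3)
  expect_equal(1 - (1 - p_annual)^5, 0.043)
  expect_error(rescale_probability(1.2, 1, 1), "\\[0, 1\\]")
})

test_that("the mortality overlay is a competing risk and is invertible", {
  m <- random_tm()
  expect_equal(unclass(apply_mortality(m, 0)), unclass(m))
  allin <- apply_mortality(m, 1)
  expect_equal(unname(allin[1:3, 4]), rep(1, 3))

  p6 <- rescale_probability(1 - 0.957^(1 / 5), 1, 0.5)
  expect_equal(p6, 0.00438, tolerance = 1e-2)
  id6 <- apply_mortality(transition_matrix(diag(4), 6), p6)
  expect_equal(unname(id6[1, ]), c(1 - p6, 0, 0, p6))

  # marginalizing dead out recovers the alive-conditional rows exactly
  set.seed(202)
  for (rep in 1:50) {
    m <- random_tm()
    p <- runif(1)
    out <- apply_mortality(m, p)
    expect_lt(max(abs(rowSums(out) - 1)), 1e-9)
    alive <- unclass(out)[1:3, 1:3] / (1 - p)
    expect_equal(alive, unclass(m)[1:3, 1:3], tolerance = 1e-12)
  }
})

test_that("schedules demand contiguity and a 6-month extrapolation matrix", {
  m6 <- random_tm(6)
  m12 <- random_tm(12)
  sched <- transition_schedule(list(m6, m12, m6), m6)
  expect_equal(sched$segments$start_month, c(0, 6, 18))
  expect_equal(sched$segments$end_month, c(6, 18, 24))
  expect_error(transition_schedule(list(m6), m12), "6-month")
})
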