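test_that("an identity schedule leaves the occupancy constant", {
  id <- transition_matrix(diag(4), 6)
  sched <- transition_schedule(list(id), id)
  init <- c(0.5, 0.3, 0.2, 0)
  tr <- run_markov(init, sched, horizon_months = 36)
  for (m in tr$month) expect_equal(unname(occupancy_at(tr, m)), init)
})

test_that("two cycles reproduce the hand-enumerated two-step distribution", {
  m <- transition_matrix(rbind(
    c(0.5, 0.3, 0.2, 0),
    c(0.1, 0.7, 0.2, 0),
    c(0.0, 0.2, 0.8, 0),
    c(0, 0, 0, 1)
  ), 6)
  sched <- transition_schedule(list(m), m)
  tr <- run_markov(c(1, 0, 0, 0), sched, horizon_months = 12)
  # brute force: all one- and two-step paths from lt5
  p1 <- unclass(m)[1, ]
  p2 <- numeric(4)
  for (k in 1:4) p2 <- p2 + p1[k] * unclass(m)[k, ]
  expect_equal(unname(occupancy_at(tr, 6)), unname(p1))
  expect_equal(unname(occupancy_at(tr, 12)), unname(p2))
})

test_that("k extrapolation cycles equal one application of the k-th power", {
  set.seed(33)
  for (rep in 1:20) {
    m <- random_tm()
    sched <- transition_schedule(list(m), m)
    k <- sample(2:8, 1)
    tr <- run_markov(c(1, 0, 0, 0), sched, horizon_months = 6 * k)
    pk <- diag(4)
    for (i in seq_len(k)) pk <- pk %*% unclass(m)
    expect_equal(unname(occupancy_at(tr, 6 * k)), unname(pk[1, ]),
                 tolerance = 1e-12)
  }
})

test_that("occupancy is conserved and death accumulates monotonically", {
  set.seed(44)
  for (rep in 1:20) {
    trial <- random_tm()
    extrap <- apply_mortality(random_tm(), runif(1, 0, 0.05))
    sched <- transition_schedule(list(trial), extrap)
    tr <- run_markov(c(1, 0, 0, 0), sched, horizon_months = 48)
    occ <- as.matrix(tr[, weight_states])
    expect_lt(max(abs(rowSums(occ) - 1)), 1e-9)
    expect_true(all(diff(tr$dead) >= -1e-12))
  }
})

test_that("a strictly positive cycle death probability strictly grows the dead state", {
  m <- apply_mortality(random_tm(), 0.004)
  sched <- transition_schedule(list(random_tm()), m)
  tr <- run_markov(c(1, 0, 0, 0), sched, horizon_months = 70)
  post <- tr$dead[tr$month >= 6]
  expect_true(all(diff(post) > 0))
})

test_that("constant mortality over 8 post-trial cycles gives the closed-form dead fraction", {
  p <- rescale_probability(1 - 0.957^(1 / 5), 1, 0.5)
  id <- transition_matrix(diag(4), 4)
  id12 <- transition_matrix(diag(4), 12)
  id6 <- transition_matrix(diag(4), 6)
  sched <- transition_schedule(list(id, id12, id6), apply_mortality(id6, p))
  tr <- run_markov(c(0.436, 0.222, 0.342, 0), sched, horizon_months = 70)
  expect_equal(occupancy_at(tr, 70)[["dead"]], 1 - (1 - p)^8)
})

test_that("traces are anchored exactly to the cohort's empirical occupancies", {
  model <- base_model()
  co <- base_cohort()
  for (a in model$arms) {
    tr <- model$traces[[a]]
    sub <- co[co$arm == a, ]
    for (m in c(4, 16, 22)) {
      expect_equal(unname(occupancy_at(tr, m)),
                   unname(empirical_occupancy(sub, m)),
                   tolerance = 1e-12)
    }
  }
})

test_that("occupancy lookups are exact stored times only", {
  id <- transition_matrix(diag(4), 6)
  sched <- transition_schedule(list(id), id)
  tr <- run_markov(c(1, 0, 0, 0), sched, horizon_months = 72)
  expect_equal(unname(occupancy_at(tr, 0)), c(1, 0, 0, 0))
  expect_equal(unname(occupancy_at(tr, 72)), c(1, 0, 0, 0))
  expect_error(occupancy_at(tr, 7), "available")
  expect_error(run_markov(c(0.5, 0.5, 0, 0), sched, horizon_months = 3),
               "horizon")
  expect_error(run_markov(c(0.7, 0.7, 0, 0), sched, 72), "summing to 1")
})
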