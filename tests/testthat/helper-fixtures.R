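# shared in-code fixtures for the suite

# a cohort_trace built directly from stored months and occupancy rows
make_trace <- function(months, occ) {
  occ <- matrix(occ, ncol = 4, byrow = TRUE)
  colnames(occ) <- weight_states
  tr <- tibble::as_tibble(as.data.frame(occ))
  tr <- dplyr::mutate(tr, month = months, .before = 1)
  for (s in weight_states) tr[[paste0("n_", s)]] <- tr[[s]] * 100000
  structure(tr, cohort_size = 100000,
            class = c("cohort_trace", class(tr)))
}

# random row-stochastic transition matrix with absorbing dead row
random_tm <- function(interval = 6) {
  m <- matrix(0, 4, 4)
  for (i in 1:3) {
    r <- stats::rgamma(4, 1)
    m[i, ] <- r / sum(r)
  }
  m[4, 4] <- 1
  transition_matrix(m, interval)
}

# minimal cohort rows with prescribed weights (single-arm unless stated)
toy_cohort <- function(w0, w4 = w0, w16, w22, arm = "individual_coaching") {
  n <- max(length(w0), length(w16), length(w22))
  tibble::tibble(
    participant_id = sprintf("p%04d", seq_len(n)),
    arm = arm, sex = "female", age_years = 55,
    weight_m0 = rep_len(w0, n), weight_m4 = rep_len(w4, n),
    weight_m16 = rep_len(w16, n), weight_m22 = rep_len(w22, n),
    htvas_m0 = 70, htvas_m16 = 70, htvas_m22 = 70,
    sf36_m0 = 70, sf36_m16 = 70, sf36_m22 = 70,
    rx_cost_monthly = 40, other_cost_monthly = 40
  )
}

# trial-sized default synthetic cohort and fitted model, built once per run
base_cohort <- local({
  value <- NULL
  function() {
    if (is.null(value)) value <<- simulate_cohort(cohort_config(seed = 42))
    value
  }
})

base_model <- local({
  value <- NULL
  function() {
    if (is.null(value)) value <<- build_cea_model(base_cohort())
    value
  }
})

# large cohort for convergence / recovery checks
big_cohort <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      value <<- simulate_cohort(cohort_config(
        n_per_arm = c(education_control = 10000L,
                      individual_coaching = 10000L),
        seed = 7
      ))
    }
    value
  }
})
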