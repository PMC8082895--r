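test_that("identical seeds reproduce identical simulations", {
  p <- default_parameters()
  s <- make_strategy("purevu", "medicare", p)
  a <- simulate_patients(p, s, n = 200, seed = 7)
  b <- simulate_patients(p, s, n = 200, seed = 7)
  expect_identical(a$states, b$states)
  expect_identical(a$cost, b$cost)
  expect_identical(a$events, b$events)
})

test_that("a certain-death toy produces the expected single path", {
  p <- toy_two_state_params(horizon = 5, p_death = 1)
  ms <- simulate_patients(p, make_strategy("soc", "medicare", p),
                          n = 1, seed = 1)
  path <- health_states()[ms$states[1, ]]
  expect_equal(path[1], "COMPLIANT_SCREENING")
  expect_true(all(path[-1] == "DEATH_OTHER"))
})

test_that("microsimulated QALYs match the geometric closed form", {
  p <- toy_two_state_params()
  ms <- simulate_patients(p, make_strategy("soc", "medicare", p),
                          n = 20000, seed = 12)
  target <- sum(0.9^(0:23))
  se <- stats::sd(ms$qaly) / sqrt(ms$n)
  expect_lt(abs(mean(ms$qaly) - target), 3 * se)
  expect_true(all(ms$cost == 0))
})

test_that("state frequencies agree with the cohort trace at every stage", {
  p <- default_parameters()
  for (arm in c("soc", "purevu")) {
    s <- make_strategy(arm, "medicare", p)
    tr <- run_cohort(p, s)
    ms <- simulate_patients(p, s, n = 4000, seed = 31)
    # simultaneous bound over 9 states x 24 stages: 4 binomial SEs
    tol <- 4 * sqrt(tr$occupancy * (1 - tr$occupancy) / ms$n) + 1 / ms$n
    expect_true(all(abs(ms$state_freq - tr$occupancy) <= tol),
                label = paste("state frequencies,", arm))
  }
})

test_that("microsim agreement holds for random valid parameter sets", {
  set.seed(55)
  for (k in 1:3) {
    p <- random_valid_params()
    s <- make_strategy(sample(c("soc", "purevu"), 1), "medicare", p)
    tr <- run_cohort(p, s)
    ms <- simulate_patients(p, s, n = 2000, seed = 100 + k)
    tol <- 4 * sqrt(tr$occupancy * (1 - tr$occupancy) / ms$n) + 2 / ms$n
    expect_true(all(abs(ms$state_freq - tr$occupancy) <= tol))
  }
})

test_that("mean simulated costs and QALYs match the cohort expectations", {
  p <- default_parameters()
  s <- make_strategy("purevu", "medicare", p)
  res <- accrue_outcomes(run_cohort(p, s), p, s)
  ms <- simulate_patients(p, s, n = 8000, seed = 91)
  expect_lt(abs(mean(ms$cost) - res$total_cost),
            3 * stats::sd(ms$cost) / sqrt(ms$n))
  expect_lt(abs(mean(ms$qaly) - res$total_qaly),
            3 * stats::sd(ms$qaly) / sqrt(ms$n))
})

test_that("per-patient cost is the sum of its event costs", {
  p <- default_parameters("private")
  p$discount_rate <- 0     # undiscounted so events reconstruct the total
  s <- make_strategy("purevu", "private", p)
  ms <- simulate_patients(p, s, n = 500, seed = 17)
  m <- s$payer_multiplier
  mk <- p$cancer_cost_multiplier
  states <- apply(ms$states, 1, function(ix) {
    tab <- tabulate(ix, nbins = 9)
    tab[5] * mk * p$cost_early_crc_annual +
      tab[6] * mk * p$cost_advanced_crc_annual +
      tab[7] * mk * p$cost_remission_annual
  })
  ev <- ms$events
  reconstructed <- states +
    ev$colonoscopies * m * (p$cost_colonoscopy_dx + p$cost_physician) +
    ev$polypectomies * m * p$cost_colonoscopy_polypectomy +
    ev$complications * m * p$cost_complication +
    ev$device_uses * m * p$cost_purevu_device
  expect_equal(ms$cost, reconstructed, tolerance = 1e-9)
})

test_that("study generator obeys its logistic success model", {
  null <- generate_study(study_spec(
    n = 10000, coef = c(intercept = 0, age = 0, sex = 0, device_used = 0,
                        cecal_intubation = 0), seed = 404))
  se <- sqrt(0.25 / nrow(null))
  expect_lt(abs(mean(null$success) - 0.5), 3 * se)

  dev <- generate_study(study_spec(
    n = 10000, coef = c(intercept = 0, age = 0, sex = 0, device_used = 1,
                        cecal_intubation = 0), seed = 405))
  tab <- table(dev$device_used, dev$success)
  log_or <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  se_or <- sqrt(sum(1 / tab))
  expect_lt(abs(log_or - 1), 3 * se_or)

  expect_identical(generate_study(study_spec(n = 50, seed = 9)),
                   generate_study(study_spec(n = 50, seed = 9)))
})
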