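# A parameter set whose every PSA distribution is a point mass at the base
# value: sampling must be the identity.
point_mass_params <- function(payer = "medicare") {
  p <- default_parameters(payer)
  p$psa_distributions <- lapply(
    stats::setNames(names(p$psa_distributions), names(p$psa_distributions)),
    function(nm) dist_spec("point", list(value = p[[nm]])))
  p
}

test_that("point-mass distributions make sampling the identity", {
  p <- point_mass_params()
  set.seed(1)
  s <- sample_parameters(p)
  for (nm in names(p$psa_distributions)) expect_identical(s[[nm]], p[[nm]])
})

test_that("beta and uniform draws respect their moments and supports", {
  p <- default_parameters("private")
  p$psa_distributions <- list(
    p_compliance_screening = dist_spec("beta",
                                       list(shape1 = 6, shape2 = 4),
                                       support = c(0, 1)),
    payer_multiplier = dist_spec("uniform", list(min = 1.63, max = 2.48),
                                 support = c(1, Inf)))
  set.seed(42)
  draws <- replicate(4000, {
    s <- sample_parameters(p)
    c(s$p_compliance_screening, s$payer_multiplier)
  })
  se <- sqrt(0.6 * 0.4 / 11) / sqrt(ncol(draws))
  expect_lt(abs(mean(draws[1, ]) - 0.6), 3 * se)
  expect_true(all(draws[2, ] >= 1.63 & draws[2, ] <= 2.48))
})

test_that("a point-mass PSA equals the deterministic base case exactly", {
  p <- point_mass_params()
  psa <- run_psa(p, n_max = 12, seed = 5)
  soc <- run_arm(p, "soc"); pv <- run_arm(p, "purevu")
  expect_true(all(psa$samples$soc_cost == soc$total_cost))
  expect_true(all(psa$samples$purevu_qaly == pv$total_qaly))
  # degenerate run converges at the earliest admissible draw
  expect_equal(psa$converged_at, 2L)
  expect_equal(diff(psa$inb_ci95), 0)
})

test_that("identical seeds reproduce a PSA byte for byte", {
  p <- default_parameters("medicare")
  a <- run_psa(p, n_max = 25, seed = 99)
  b <- run_psa(p, n_max = 25, seed = 99)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(a$samples, fa, row.names = FALSE)
  utils::write.csv(b$samples, fb, row.names = FALSE)
  expect_identical(readLines(fa), readLines(fb))
  expect_false(isTRUE(all.equal(run_psa(p, n_max = 25, seed = 100)$samples,
                                a$samples)))
})

test_that("the convergence monitor never fires before the second draw", {
  expect_true(is.na(prepcea:::.icer_convergence(c(1), 0.001, 10)))
  traj <- rep(100, 50)
  expect_gte(prepcea:::.icer_convergence(traj, 0.001, 10), 2)
  # a trajectory that keeps moving by more than the tolerance never converges
  moving <- 100 * cumprod(rep(1.01, 60))
  expect_true(is.na(prepcea:::.icer_convergence(moving, 0.001, 10)))
})

test_that("the cost-effectiveness plane summary partitions the draws", {
  p <- default_parameters()
  psa <- run_psa(p, n_max = 40, seed = 3)
  s <- summarize_ce_plane(psa)
  expect_equal(sum(s$quadrant_fractions), 1)
  expect_equal(s$n, 40)
  expect_error(summarize_ce_plane(list(samples = psa$samples[1, ])),
               "at least 2")
})

test_that("percentile intervals recover injected normal net benefits", {
  set.seed(8)
  n <- 10000
  inb <- stats::rnorm(n, 900, 100)
  fake <- list(samples = data.frame(
    draw = 1:n, soc_cost = 0, soc_qaly = 1,
    purevu_cost = -inb, purevu_qaly = 1, inb = inb), wtp = 0)
  s <- summarize_ce_plane(fake, wtp = 0)
  # quantile-estimator SE: sqrt(p(1-p)/n)/f(q)
  se_q <- sqrt(0.025 * 0.975 / n) / stats::dnorm(stats::qnorm(0.025))
  expect_lt(abs(s$inb_ci95[1] - (900 - 1.96 * 100)), 3 * se_q * 100)
  expect_lt(abs(s$inb_ci95[2] - (900 + 1.96 * 100)), 3 * se_q * 100)
  expect_gt(s$prob_positive_inb, 0.99)
})

test_that("a strategy dominant over the whole sampled support always nets benefit", {
  # only the device price varies, and it stays below the crossing point, so
  # every draw keeps the device arm cheaper and more effective
  p <- default_parameters("medicare")
  p$psa_distributions <- list(
    cost_purevu_device = dist_spec("uniform", list(min = 500, max = 1000),
                                   support = c(0, Inf)))
  psa <- run_psa(p, n_max = 60, seed = 21)
  expect_equal(psa$prob_positive_inb, 1.0)
})
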