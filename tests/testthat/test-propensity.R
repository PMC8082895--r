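test_that("the null logistic model is recovered on null data", {
  d <- generate_study(study_spec(
    n = 5000, coef = c(intercept = 0, age = 0, sex = 0, device_used = 0,
                       cecal_intubation = 0), seed = 101))
  fit <- fit_logistic(d, c("age", "sex", "device_used", "cecal_intubation"))
  expect_true(fit$converged)
  expect_true(all(abs(fit$wald$estimate) <= 3 * fit$wald$se))
  expect_gte(fit$log_likelihood, fit$null_log_likelihood)
})

test_that("generating coefficients are recovered within 3 standard errors", {
  truth <- c(intercept = -3.0, age = 0.05, sex = 0.8, device_used = 0.5,
             cecal_intubation = 1.0)
  d <- generate_study(study_spec(n = 5000, coef = truth, seed = 202))
  fit <- fit_logistic(d, c("age", "sex", "device_used", "cecal_intubation"))
  est <- fit$wald$estimate
  se <- fit$wald$se
  expect_true(all(abs(est - unname(truth)) <= 3 * se))
})

test_that("the fit agrees with a direct likelihood maximiser", {
  d <- generate_study(study_spec(n = 200, seed = 77))
  fit <- fit_logistic(d, c("age", "sex"))
  # independent maximiser: BFGS start, Newton-Raphson polish
  X <- cbind(1, d$age, d$sex)
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    -sum(d$success * eta - log1p(exp(eta)))
  }
  b <- stats::optim(c(0, 0, 0), nll, method = "BFGS",
                    control = list(maxit = 500))$par
  for (it in 1:25) {
    mu <- stats::plogis(as.numeric(X %*% b))
    score <- crossprod(X, d$success - mu)
    H <- crossprod(X * (mu * (1 - mu)), X)
    b <- b + solve(H, score)[, 1]
  }
  expect_equal(unname(fit$coefficients), b, tolerance = 1e-6)
  expect_equal(fit$log_likelihood, -nll(b), tolerance = 1e-10)
})

test_that("degenerate and separated data are rejected", {
  d <- generate_study(study_spec(n = 50, seed = 1))
  d$success <- 1
  expect_error(fit_logistic(d, "age"), "constant")
  sep <- data.frame(age = c(1:10, 31:40),
                    success = rep(c(0, 1), each = 10))
  expect_error(fit_logistic(sep, "age"), "separation")
  expect_error(fit_logistic(d[1:5, ], "age"), "at least 10")
})

test_that("scores apply the logistic link per record", {
  m0 <- structure(list(coefficients = c("(Intercept)" = 0, age = 0),
                       converged = TRUE, covariate_names = "age"),
                  class = "propensity_model")
  d <- data.frame(age = c(40, 60, 80))
  expect_equal(propensity_score(m0, d), rep(0.5, 3))
  m1 <- m0
  m1$coefficients <- c("(Intercept)" = log(3), age = 0)
  expect_equal(propensity_score(m1, d), rep(0.75, 3))
  m2 <- m0
  m2$coefficients <- c("(Intercept)" = 0, age = 0.1)
  expect_true(all(diff(propensity_score(m2, d)) > 0))
  expect_error(propensity_score(m0, data.frame(sex = 1)), "lack covariate")
})

test_that("greedy matching respects the caliper and picks nearest controls", {
  ms <- match_scores(stats::plogis(0), stats::plogis(c(0.1, 5)),
                     caliper = 0.2)
  expect_equal(nrow(ms$pairs), 1)
  expect_equal(ms$pairs$control, 1)
  expect_equal(ms$unmatched_treated, 0)

  same <- match_scores(c(0.3, 0.5, 0.7), c(0.3, 0.5, 0.7), caliper = 0.01)
  expect_equal(nrow(same$pairs), 3)
  expect_equal(same$unmatched_treated, 0)
  expect_true(all(same$pairs$distance == 0))

  set.seed(5)
  for (k in 1:20) {
    st <- stats::runif(6, 0.2, 0.8); sc <- stats::runif(9, 0.2, 0.8)
    ms <- match_scores(st, sc, caliper = 0.3)
    expect_true(all(ms$pairs$distance <= 0.3 + 1e-12))
    expect_lte(nrow(ms$pairs), min(length(st), length(sc)))
    expect_true(!anyDuplicated(ms$pairs$control))
  }
})

test_that("greedy matching attains the assignment oracle on clean instances", {
  set.seed(31)
  for (k in 1:15) {
    # non-overlapping instance: treated units spaced well apart, each with
    # exactly one control inside the caliper and distinct gaps
    lt <- cumsum(stats::runif(4, 0.6, 1.2)) - 2.5
    lc <- lt + stats::runif(4, -0.05, 0.05)
    extra <- lt + sample(c(-0.4, 0.4), 4, replace = TRUE)
    ms <- match_scores(stats::plogis(lt), stats::plogis(c(lc, extra)),
                       caliper = 0.1)
    oracle <- match_oracle(lt, c(lc, extra), 0.1)
    expect_equal(nrow(ms$pairs), oracle$pairs)
    expect_equal(sum(ms$pairs$distance), oracle$dist, tolerance = 1e-9)
  }
  # generic instances: greedy never beats the oracle
  for (k in 1:15) {
    lt <- stats::runif(4, -1, 1); lc <- stats::runif(6, -1, 1)
    ms <- match_scores(stats::plogis(lt), stats::plogis(lc), caliper = 0.5)
    oracle <- match_oracle(lt, lc, 0.5)
    expect_lte(nrow(ms$pairs), oracle$pairs)
    if (nrow(ms$pairs) == oracle$pairs) {
      expect_gte(sum(ms$pairs$distance), oracle$dist - 1e-9)
    }
  }
})

test_that("matching improves covariate balance on imbalanced synthetic data", {
  set.seed(66)
  n <- 600
  treated <- data.frame(age = stats::rnorm(n, 66, 6),
                        sex = stats::rbinom(n, 1, 0.6))
  control <- data.frame(age = stats::rnorm(2 * n, 60, 6),
                        sex = stats::rbinom(2 * n, 1, 0.45))
  both <- rbind(cbind(treated, z = 1), cbind(control, z = 0))
  tm <- fit_logistic(both, c("age", "sex"), outcome = "z")
  sc <- propensity_score(tm, both)
  ms <- match_scores(sc[both$z == 1], sc[both$z == 0])
  smd_before <- (mean(treated$age) - mean(control$age)) /
    sqrt((stats::var(treated$age) + stats::var(control$age)) / 2)
  bal <- balance_check(treated, control, ms, c("age", "sex"))
  expect_lt(abs(bal$smd[bal$covariate == "age"]), abs(smd_before))
  expect_lt(abs(bal$smd[bal$covariate == "age"]), 0.25)
})

test_that("balance is zero for identical matched samples", {
  d <- data.frame(age = c(60, 62), sex = c(1, 0))
  ms <- list(pairs = data.frame(treated = 1:2, control = 1:2))
  bal <- balance_check(d, d, ms, c("age", "sex"))
  expect_equal(bal$smd, c(0, 0))
  one <- balance_check(d[1, , drop = FALSE], d[1, , drop = FALSE],
                       list(pairs = data.frame(treated = 1, control = 1)),
                       "age")
  expect_equal(one$smd, 0)
  expect_true(one$degenerate)
})
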