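# One draw from a dist_spec, clipped to its support by rejection.
.sample_dist <- function(spec, max_retries = 1000L) {
  draw <- function() {
    p <- spec$params
    switch(spec$kind,
      beta = stats::rbeta(1, p$shape1, p$shape2),
      gamma = stats::rgamma(1, shape = p$shape, scale = p$scale),
      uniform = stats::runif(1, p$min, p$max),
      triangular = {
        # inverse-CDF sampling of the triangular distribution
        u <- stats::runif(1)
        fc <- (p$mode - p$min) / (p$max - p$min)
        if (u < fc) p$min + sqrt(u * (p$max - p$min) * (p$mode - p$min))
        else p$max - sqrt((1 - u) * (p$max - p$min) * (p$max - p$mode))
      },
      normal = stats::rnorm(1, p$mean, p$sd),
      point = p$value
    )
  }
  if (is.null(spec$support)) return(draw())
  for (k in seq_len(max_retries)) {
    x <- draw()
    if (x >= spec$support[1] && x <= spec$support[2]) return(x)
  }
  stop("distribution draw fell outside its support ", max_retries,
       " times; check the distribution configuration", call. = FALSE)
}

#' Draw one parameter set from its PSA distributions
#'
#' Fields carrying a distribution in `psa_distributions` are replaced by
#' independent draws clipped to their supports; all other fields keep their
#' base values. The sampled set must pass validation.
#'
#' @param base Validated parameter set.
#' @return A validated `cea_parameters` draw.
#' @export
#' @examples
#' set.seed(1)
#' sample_parameters(default_parameters())$p_compliance_screening
sample_parameters <- function(base) {
  p <- base
  for (nm in names(base$psa_distributions)) {
    p[[nm]] <- .sample_dist(base$psa_distributions[[nm]])
  }
  rep <- validate_parameters(p)
  if (!is_valid(rep))
    stop("sampled parameter set failed validation: ",
         paste0(rep$errors$field, collapse = ", "), call. = FALSE)
  p
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: at each draw a
#' parameter set is sampled from the configured distributions, both arms
#' are run on the **same** draw (common random parameters), and the running
#' mean of the ICER is monitored for convergence. The convergence rule
#' follows the practice of stopping Monte-Carlo cost-effectiveness runs
#' when the primary output stops moving: the run is declared converged at
#' the first draw after which the relative change of the running mean ICER
#' stays at or below `convergence_tol` for `window` consecutive draws.
#' Draws with an undefined ICER (|dQALY| < 1e-9) are excluded from the
#' running mean and counted.
#'
#' @param base Validated parameter set (its `psa_distributions` drive the
#'   sampling; its payer prices both arms).
#' @param n_max Number of draws (default 10000; 1728 reproduces the
#'   published run length).
#' @param convergence_tol Relative change tolerance for the running-mean
#'   ICER (default 0.001, i.e. the 0.1% rule).
#' @param seed Integer seed; the run is reproducible given the seed.
#' @param wtp Willingness to pay per QALY used for the per-draw incremental
#'   net benefit (default 50000).
#' @param window Consecutive-draw window over which the rule must hold
#'   (default 100).
#' @return An object of class `psa_result`: `samples` (data frame with one
#'   row per draw: sampled parameter columns, per-arm cost/QALY, `inb`),
#'   `mean_icer_trajectory`, `converged_at` (draw index or `NA`),
#'   `n_icer_excluded`, `inb_mean`, `inb_ci95`, `prob_positive_inb`, `wtp`.
#' @export
#' @examples
#' \donttest{
#' run_psa(default_parameters(), n_max = 100, seed = 1)
#' }
run_psa <- function(base, n_max = 10000L, convergence_tol = 0.001,
                    seed = NULL, wtp = 50000, window = 100L) {
  .assert_valid(base)
  if (n_max < 2) stop("n_max must be at least 2", call. = FALSE)
  if (convergence_tol <= 0) stop("convergence_tol must be positive",
                                 call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  sampled_fields <- names(base$psa_distributions)
  draws <- matrix(NA_real_, n_max, length(sampled_fields),
                  dimnames = list(NULL, sampled_fields))
  soc_cost <- soc_qaly <- pv_cost <- pv_qaly <- inb <- numeric(n_max)
  icer_sum <- 0
  icer_n <- 0L
  traj <- rep(NA_real_, n_max)

  for (k in seq_len(n_max)) {
    p <- sample_parameters(base)
    if (length(sampled_fields))
      draws[k, ] <- vapply(sampled_fields, function(f) p[[f]], numeric(1))
    soc <- run_arm(p, "soc")
    pv <- run_arm(p, "purevu")
    soc_cost[k] <- soc$total_cost; soc_qaly[k] <- soc$total_qaly
    pv_cost[k] <- pv$total_cost; pv_qaly[k] <- pv$total_qaly
    dq <- pv$total_qaly - soc$total_qaly
    dc <- pv$total_cost - soc$total_cost
    inb[k] <- wtp * dq - dc
    if (abs(dq) >= 1e-9) {
      icer_sum <- icer_sum + dc / dq
      icer_n <- icer_n + 1L
    }
    traj[k] <- if (icer_n > 0) icer_sum / icer_n else NA_real_
  }

  converged_at <- .icer_convergence(traj, convergence_tol, window)

  samples <- data.frame(draw = seq_len(n_max), draws,
                        soc_cost = soc_cost, soc_qaly = soc_qaly,
                        purevu_cost = pv_cost, purevu_qaly = pv_qaly,
                        inb = inb, check.names = FALSE)
  structure(
    list(samples = samples,
         mean_icer_trajectory = traj,
         converged_at = converged_at,
         n_icer_excluded = n_max - icer_n,
         inb_mean = mean(inb),
         inb_ci95 = unname(stats::quantile(inb, c(0.025, 0.975))),
         prob_positive_inb = mean(inb > 0),
         wtp = wtp),
    class = "psa_result"
  )
}

# First index i >= 2 such that the relative change of the running mean is
# <= tol for all draws in (i, i + window] (window truncated at n).
.icer_convergence <- function(traj, tol, window) {
  n <- length(traj)
  if (n < 2) return(NA_integer_)
  rel <- rep(NA_real_, n)
  for (j in 2:n) {
    if (is.na(traj[j]) || is.na(traj[j - 1])) next
    denom <- abs(traj[j - 1])
    rel[j] <- if (denom > 0) abs(traj[j] - traj[j - 1]) / denom
              else as.numeric(traj[j] != traj[j - 1])
  }
  ok <- !is.na(rel) & rel <= tol
  for (i in 2:n) {
    upper <- min(n, i + window)
    if (i + 1 > upper) break
    if (all(ok[(i + 1):upper])) return(i)
  }
  NA_integer_
}

#' @export
print.psa_result <- function(x, ...) {
  n <- nrow(x$samples)
  cat("<psa_result> ", n, " draws; INB mean $", round(x$inb_mean),
      " [", round(x$inb_ci95[1]), ", ", round(x$inb_ci95[2]),
      "] at WTP $", x$wtp, "/QALY\n", sep = "")
  cat("  P(INB > 0) = ", round(x$prob_positive_inb, 3),
      "; running-mean ICER ",
      if (is.na(x$converged_at)) "did not meet the convergence rule"
      else paste0("converged at draw ", x$converged_at), "\n", sep = "")
  invisible(x)
}

#' Cost-effectiveness-plane summary of a PSA
#'
#' @param result A `psa_result`.
#' @param wtp Willingness to pay per QALY at which to recompute the INB
#'   summary (defaults to the run's own).
#' @return List with `quadrant_fractions` (named fractions of draws in the
#'   four incremental-plane quadrants, boundary draws counted by
#'   non-negative sign), `inb_mean`, `inb_ci95` (percentile 95% interval),
#'   `prob_positive_inb`, `n`.
#' @export
summarize_ce_plane <- function(result, wtp = result$wtp) {
  s <- result$samples
  if (is.null(s) || nrow(s) < 2)
    stop("at least 2 PSA samples are required", call. = FALSE)
  dc <- s$purevu_cost - s$soc_cost
  dq <- s$purevu_qaly - s$soc_qaly
  inb <- wtp * dq - dc
  quadrant <- ifelse(dq >= 0,
                     ifelse(dc >= 0, "ne_more_costly_more_effective",
                            "se_less_costly_more_effective"),
                     ifelse(dc >= 0, "nw_more_costly_less_effective",
                            "sw_less_costly_less_effective"))
  lv <- c("ne_more_costly_more_effective", "se_less_costly_more_effective",
          "nw_more_costly_less_effective", "sw_less_costly_less_effective")
  qf <- table(factor(quadrant, levels = lv)) / length(quadrant)
  list(
    quadrant_fractions = as.numeric(qf) |> stats::setNames(lv),
    inb_mean = mean(inb),
    inb_ci95 = unname(stats::quantile(inb, c(0.025, 0.975))),
    prob_positive_inb = mean(inb > 0),
    n = nrow(s)
  )
}
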