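# Re-run both arms with one field replaced; shared by sweep and threshold.
.arm_pair_at <- function(params, parameter, value, payer) {
  if (!parameter %in% names(params) || !is.numeric(params[[parameter]]))
    stop("unknown or non-numeric parameter: ", parameter, call. = FALSE)
  p <- params
  p[[parameter]] <- value
  rep <- validate_parameters(p)
  if (!is_valid(rep))
    stop("invalid value ", value, " for ", parameter, ": ",
         paste(rep$errors$message[rep$errors$field == parameter],
               collapse = "; "),
         call. = FALSE)
  list(soc = run_arm(p, "soc", payer), purevu = run_arm(p, "purevu", payer))
}

#' One-way sensitivity sweep
#'
#' Re-runs both arms over a grid of values of a single parameter, holding
#' every other input at its base-case value.
#'
#' @param params Validated base-case parameter set.
#' @param parameter Name of a numeric field of the schema (e.g.
#'   `"p_compliance_screening"`, `"cost_purevu_device"`).
#' @param grid Numeric values to evaluate; sorted increasingly before use.
#' @param payer Payer at which to cost both arms; defaults to the parameter
#'   set's payer.
#' @return An object of class `sweep_result`: data frame with one row per
#'   grid value and columns `value`, `soc_cost`, `soc_qaly`, `purevu_cost`,
#'   `purevu_qaly`, `saving` (SOC minus device-arm lifetime cost),
#'   `soc_cost_per_qaly`, `purevu_cost_per_qaly`, `cost_per_qaly_saving`.
#' @export
#' @examples
#' \donttest{
#' one_way_sweep(default_parameters("private"), "p_compliance_screening",
#'               seq(0.2, 0.8, by = 0.1))
#' }
one_way_sweep <- function(params, parameter, grid, payer = params$payer) {
  .assert_valid(params)
  if (!length(grid)) stop("empty grid", call. = FALSE)
  grid <- sort(unique(as.numeric(grid)))
  rows <- lapply(grid, function(v) {
    arms <- .arm_pair_at(params, parameter, v, payer)
    data.frame(
      value = v,
      soc_cost = arms$soc$total_cost,
      soc_qaly = arms$soc$total_qaly,
      purevu_cost = arms$purevu$total_cost,
      purevu_qaly = arms$purevu$total_qaly,
      saving = arms$soc$total_cost - arms$purevu$total_cost,
      soc_cost_per_qaly = arms$soc$total_cost / arms$soc$total_qaly,
      purevu_cost_per_qaly = arms$purevu$total_cost / arms$purevu$total_qaly
    )
  })
  out <- do.call(rbind, rows)
  out$cost_per_qaly_saving <- out$soc_cost_per_qaly - out$purevu_cost_per_qaly
  structure(out, parameter = parameter, payer = payer,
            class = c("sweep_result", "data.frame"))
}

#' Threshold analysis by bisection
#'
#' Finds the value of a parameter at which standard of care stops being the
#' more expensive strategy: the sign change of the deterministic lifetime
#' cost difference (SOC minus device arm), located by bisection. QALYs play
#' no role in the predicate, mirroring the "less expensive" phrasing of
#' threshold reporting.
#'
#' @param params Validated base-case parameter set.
#' @param parameter Name of the swept field.
#' @param bracket Length-2 numeric `(low, high)`; the cost difference must
#'   change sign over the bracket.
#' @param tol Bracket width at which bisection stops (default: 0.005 for
#'   probability-scaled fields, 1 for others).
#' @param payer Payer at which to cost both arms.
#' @return An object of class `threshold_result`: list with `parameter`,
#'   `threshold` (final bracket midpoint), `bracket`, `tolerance`,
#'   `predicate`, `payer`.
#' @export
#' @examples
#' \donttest{
#' find_threshold(default_parameters(), "cost_purevu_device", c(0, 5000),
#'                tol = 1)
#' }
find_threshold <- function(params, parameter, bracket, tol = NULL,
                           payer = params$payer) {
  .assert_valid(params)
  stopifnot(length(bracket) == 2)
  lo <- min(bracket); hi <- max(bracket)
  if (is.null(tol)) {
    tol <- if (grepl("^(p_|sens_|spec_|sex_)", parameter)) 0.005 else 1
  }
  if (tol <= 0) stop("tol must be positive", call. = FALSE)

  g <- function(v) {
    arms <- .arm_pair_at(params, parameter, v, payer)
    arms$soc$total_cost - arms$purevu$total_cost
  }
  g_lo <- g(lo); g_hi <- g(hi)
  if (g_lo == 0) hi <- lo      # equality at an endpoint: report it directly
  else if (g_hi == 0) lo <- hi
  else if (sign(g_lo) == sign(g_hi)) {
    stop("cost difference does not change sign over the bracket [",
         lo, ", ", hi, "]; no threshold in range", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    g_mid <- g(mid)
    if (g_mid == 0) { lo <- mid; hi <- mid; break }
    if (sign(g_mid) == sign(g_lo)) { lo <- mid; g_lo <- g_mid }
    else hi <- mid
  }
  structure(
    list(parameter = parameter, threshold = (lo + hi) / 2,
         bracket = c(lo, hi), tolerance = tol,
         predicate = "sign(soc_cost - purevu_cost)", payer = payer),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("<threshold_result> ", x$parameter, " = ",
      signif(x$threshold, 6), " (", x$payer, "; bracket [",
      signif(x$bracket[1], 6), ", ", signif(x$bracket[2], 6),
      "], tol ", x$tolerance, ")\n", sep = "")
  invisible(x)
}
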