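#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes the incremental cost and QALYs of an intervention over a
#' comparator run under the same parameter set, the ICER where defined, and
#' the dominance classification by cost-effectiveness-plane quadrant.
#'
#' @param intervention,comparator `arm_result` objects (or any list with
#'   `total_cost` and `total_qaly`).
#' @return An object of class `icer_result`: `delta_cost`, `delta_qaly`,
#'   `icer` (`NA` when `delta_qaly` is 0), and `dominance`, one of
#'   `"intervention_dominates"` (cheaper and more effective),
#'   `"comparator_dominates"` (dearer and less effective),
#'   `"tradeoff_ne_quadrant"` (dearer, more effective),
#'   `"tradeoff_sw_quadrant"` (cheaper, less effective).
#' @export
#' @examples
#' a <- list(total_cost = 6070, total_qaly = 15.25)
#' b <- list(total_cost = 6903, total_qaly = 15.10)
#' compare_arms(a, b)
compare_arms <- function(intervention, comparator) {
  delta_cost <- intervention$total_cost - comparator$total_cost
  delta_qaly <- intervention$total_qaly - comparator$total_qaly
  icer <- if (delta_qaly != 0) delta_cost / delta_qaly else NA_real_
  dominance <-
    if (delta_cost < 0 && delta_qaly > 0) "intervention_dominates"
    else if (delta_cost > 0 && delta_qaly < 0) "comparator_dominates"
    else if (delta_cost == 0 && delta_qaly == 0) "indifferent"
    else if (delta_cost >= 0) "tradeoff_ne_quadrant"
    else "tradeoff_sw_quadrant"
  structure(
    list(delta_cost = delta_cost, delta_qaly = delta_qaly, icer = icer,
         dominance = dominance),
    class = "icer_result"
  )
}

#' @export
print.icer_result <- function(x, ...) {
  cat("<icer_result> dCost $", round(x$delta_cost, 2), ", dQALY ",
      round(x$delta_qaly, 4), "\n", sep = "")
  cat("  ", if (is.na(x$icer)) "ICER undefined (equal QALYs)"
      else paste0("ICER $", round(x$icer), "/QALY"),
      "; ", x$dominance, "\n", sep = "")
  invisible(x)
}

#' Incremental net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost`: positive values favour the intervention
#' at the given willingness to pay.
#'
#' @param intervention,comparator `arm_result` objects.
#' @param wtp Willingness to pay per QALY, non-negative.
#' @return Net benefit in money units.
#' @export
#' @examples
#' incremental_net_benefit(list(total_cost = 6070, total_qaly = 15.25),
#'                         list(total_cost = 6903, total_qaly = 15.10),
#'                         wtp = 50000)
incremental_net_benefit <- function(intervention, comparator, wtp) {
  if (any(wtp < 0)) stop("willingness to pay must be non-negative",
                         call. = FALSE)
  delta_cost <- intervention$total_cost - comparator$total_cost
  delta_qaly <- intervention$total_qaly - comparator$total_qaly
  wtp * delta_qaly - delta_cost
}

#' Average cost per QALY of one arm
#'
#' The per-arm ratio reported in parentheses in the results tables —
#' distinct from the pairwise ICER.
#'
#' @param cost Lifetime discounted cost.
#' @param qaly Lifetime discounted QALYs, positive.
#' @param round_dollars Round to the nearest dollar (the reporting
#'   convention)? Default `TRUE`.
#' @return Cost per QALY.
#' @export
#' @examples
#' cost_per_qaly(6903, 15.10)
cost_per_qaly <- function(cost, qaly, round_dollars = TRUE) {
  if (any(qaly <= 0)) stop("QALYs must be positive", call. = FALSE)
  r <- cost / qaly
  if (round_dollars) round(r) else r
}

#' National annual savings projection
#'
#' Scales a per-patient lifetime saving to the national volume of
#' inadequately prepped colonoscopies: `n * inadequate_rate *
#' per_patient_saving`.
#'
#' @param n Annual colonoscopy volume.
#' @param inadequate_rate Fraction inadequately prepped, in `[0, 1]`.
#' @param per_patient_saving Lifetime discounted saving per affected
#'   patient.
#' @return Total projected saving.
#' @export
#' @examples
#' national_savings(15e6, 0.25, 833)
national_savings <- function(n, inadequate_rate, per_patient_saving) {
  stopifnot(n >= 0, inadequate_rate >= 0, inadequate_rate <= 1,
            per_patient_saving >= 0)
  n * inadequate_rate * per_patient_saving
}

#' Patients failing screening guidelines after inadequate prep
#'
#' `n * inadequate_rate * nonrepeat_complement`: the annual number of
#' patients whose colonoscopy was inadequately prepped and who do not
#' return for the recommended repeat exam.
#'
#' @param n Annual colonoscopy volume.
#' @param inadequate_rate Fraction inadequately prepped, in `[0, 1]`.
#' @param nonrepeat_complement One minus the repeat rate, in `[0, 1]`.
#' @return Patient count.
#' @export
#' @examples
#' patients_failing_guidelines(2e6, 0.25, 0.80)
patients_failing_guidelines <- function(n, inadequate_rate,
                                        nonrepeat_complement) {
  stopifnot(n >= 0, inadequate_rate >= 0, inadequate_rate <= 1,
            nonrepeat_complement >= 0, nonrepeat_complement <= 1)
  n * inadequate_rate * nonrepeat_complement
}
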