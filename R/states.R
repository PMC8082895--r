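#' Health states of the screening cohort model
#'
#' The model tracks a cohort of average-risk 60-year-olds through nine
#' mutually exclusive health states:
#'
#' * `COMPLIANT_SCREENING` — engaged with the decennial screening programme.
#' * `NONCOMPLIANT_POST_COLONOSCOPY` — had at least one colonoscopy but lapsed
#'   from the programme (in this model, after an inadequately prepped exam
#'   that was never repeated).
#' * `NONCOMPLIANT_WITH_SYSTEM` — never engages with screening.
#' * `ADENOMA_SURVEILLANCE` — post-polypectomy surveillance at a shortened
#'   colonoscopy interval.
#' * `EARLY_CRC` — diagnosed early-stage colorectal cancer, under treatment.
#' * `ADVANCED_CRC` — advanced/metastatic colorectal cancer.
#' * `REMISSION` — early-stage cancer successfully treated.
#' * `DEATH_CRC`, `DEATH_OTHER` — absorbing death states.
#'
#' @return Character vector of the nine state labels, in canonical order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c(
    "COMPLIANT_SCREENING",
    "NONCOMPLIANT_POST_COLONOSCOPY",
    "NONCOMPLIANT_WITH_SYSTEM",
    "ADENOMA_SURVEILLANCE",
    "EARLY_CRC",
    "ADVANCED_CRC",
    "REMISSION",
    "DEATH_CRC",
    "DEATH_OTHER"
  )
}

#' Absorbing states of the model
#'
#' @return Character vector of the two absorbing (death) states.
#' @export
absorbing_states <- function() {
  c("DEATH_CRC", "DEATH_OTHER")
}

# Internal index helpers; the canonical ordering above is relied on throughout.
.S <- function() length(health_states())

.state_idx <- function(state) {
  i <- match(state, health_states())
  if (anyNA(i)) {
    stop("unknown health state(s): ", paste(state[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  i
}
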