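#' The eleven Fabry disease model states
#'
#' The model follows the natural history of Fabry disease through eleven
#' health states: an asymptomatic state, acroparesthesia (neuropathic pain
#' without organ involvement), a symptomatic state (left ventricular
#' hypertrophy, chronic kidney disease stages 1-4 or white matter lesions),
#' the three single end-organ complications (end-stage renal disease,
#' cardiac complication, cerebrovascular accident), their three pairwise
#' combinations, the triple combination, and death.
#'
#' Each state carries the number of end-organ complications (0-3) and the
#' cluster used for utility and cost lookup. Utilities and annual costs are
#' observed per cluster rather than per state because patient numbers in
#' the multi-complication states are small.
#'
#' @return A data frame with one row per state and columns `name`,
#'   `complication_count` and `cluster`.
#' @export
#' @examples
#' fabry_states()
fabry_states <- function() {
  data.frame(
    name = c("asymptomatic", "acroparesthesia", "symptoms",
             "esrd", "cardiac", "cva",
             "esrd_cardiac", "esrd_cva", "cardiac_cva",
             "esrd_cardiac_cva", "death"),
    complication_count = c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, NA_integer_),
    cluster = c("asymptomatic", "acro_or_symptoms", "acro_or_symptoms",
                "single_complication", "single_complication",
                "single_complication",
                "multiple_complications", "multiple_complications",
                "multiple_complications", "multiple_complications",
                "dead"),
    stringsAsFactors = FALSE
  )
}

#' State-name constants
#'
#' @return Character vector of the eleven state names, in model order.
#' @export
state_names <- function() fabry_states()$name

# states counted as free of end-organ damage
yfeod_states <- function() c("asymptomatic", "acroparesthesia", "symptoms")

#' Allowed transitions of the Fabry disease model
#'
#' Disease progression is one-directional: asymptomatic patients develop
#' acroparesthesia or symptoms, acroparesthesia progresses to symptoms, the
#' symptomatic state progresses to one of the three single complications,
#' single complications gain a second, and double complications gain the
#' third. A gained complication is never lost, with one exception: patients
#' with end-stage renal disease may return to the symptomatic state after a
#' kidney transplant. Every living state can transition to death; death is
#' absorbing.
#'
#' @param transplant Keep the ESRD to symptoms kidney-transplant return
#'   edge (default `TRUE`).
#' @return A data frame with columns `from` and `to`, excluding the
#'   death edges (every living state implicitly has one).
#' @export
fabry_edges <- function(transplant = TRUE) {
  e <- rbind(
    c("asymptomatic", "acroparesthesia"),
    c("asymptomatic", "symptoms"),
    c("acroparesthesia", "symptoms"),
    c("symptoms", "esrd"),
    c("symptoms", "cardiac"),
    c("symptoms", "cva"),
    c("esrd", "esrd_cardiac"),
    c("esrd", "esrd_cva"),
    c("cardiac", "esrd_cardiac"),
    c("cardiac", "cardiac_cva"),
    c("cva", "esrd_cva"),
    c("cva", "cardiac_cva"),
    c("esrd_cardiac", "esrd_cardiac_cva"),
    c("esrd_cva", "esrd_cardiac_cva"),
    c("cardiac_cva", "esrd_cardiac_cva")
  )
  out <- data.frame(from = e[, 1], to = e[, 2], stringsAsFactors = FALSE)
  if (transplant) {
    out <- rbind(out, data.frame(from = "esrd", to = "symptoms"))
  }
  out
}

#' Map states to utility/cost clusters
#'
#' @param states Character vector of state names.
#' @return Character vector of cluster labels.
#' @export
state_cluster <- function(states) {
  st <- fabry_states()
  idx <- match(states, st$name)
  if (anyNA(idx)) {
    stop("unknown state(s): ", paste(states[is.na(idx)], collapse = ", "))
  }
  st$cluster[idx]
}
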