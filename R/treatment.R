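#' Cumulative risk over a duration under a constant annual probability
#'
#' @param p_annual Annual event probability in \[0,1\].
#' @param years Duration in years (> 0).
#' @return `1 - (1 - p_annual)^years`.
#' @export
cumulative_risk <- function(p_annual, years) {
  if (any(p_annual < 0 | p_annual > 1)) stop("p_annual must be in [0,1]")
  if (any(years <= 0)) stop("years must be > 0")
  1 - (1 - p_annual)^years
}

#' Relative risk reduction over a median treatment duration
#'
#' The treatment effect of enzyme replacement therapy is reported as an
#' odds ratio per treatment-year (ERT duration, not ERT as such, affects
#' the odds of progression). The odds ratio therefore compounds
#' multiplicatively over the median treatment duration in the state:
#' the untreated cumulative risk over the duration is converted to odds,
#' multiplied by `or^duration`, converted back to a treated cumulative
#' risk, and expressed as a relative risk reduction.
#'
#' @param p_annual_untreated Untreated annual transition probability,
#'   strictly inside (0,1).
#' @param or_per_year Odds ratio per treatment-year (> 0).
#' @param duration Median treatment duration in years (> 0).
#' @return The cumulative relative risk reduction over `duration`.
#' @export
rrr_over_duration <- function(p_annual_untreated, or_per_year, duration) {
  if (or_per_year <= 0) stop("odds ratio must be > 0")
  p0 <- cumulative_risk(p_annual_untreated, duration)
  if (p0 <= 0 || p0 >= 1) {
    stop("cumulative untreated risk is 0 or 1; odds undefined")
  }
  odds1 <- p0 / (1 - p0) * or_per_year^duration
  p1 <- odds1 / (1 + odds1)
  1 - p1 / p0
}

#' Per-cycle relative risk reduction
#'
#' De-cumulates the treated risk over the median duration back to a single
#' model year (constant hazard within the window) and expresses it
#' relative to the untreated annual probability.
#'
#' @param p_annual_untreated Untreated annual probability.
#' @param rrr_cumulative Output of [rrr_over_duration()].
#' @param duration The same duration in years.
#' @return The per-cycle relative risk reduction.
#' @export
per_cycle_rrr <- function(p_annual_untreated, rrr_cumulative, duration) {
  if (duration <= 0) stop("duration must be > 0")
  p0 <- cumulative_risk(p_annual_untreated, duration)
  p1_cum <- p0 * (1 - rrr_cumulative)
  p1 <- 1 - (1 - p1_cum)^(1 / duration)
  1 - p1 / p_annual_untreated
}

#' Treated annual probability
#'
#' The annual transition probability under ERT is the untreated
#' probability multiplied by one minus the per-cycle relative risk
#' reduction.
#'
#' @param p_untreated Untreated annual probability in \[0,1\].
#' @param rrr_per_cycle Per-cycle relative risk reduction (<= 1; negative
#'   values, i.e. harm, are allowed and clipped at probability 1).
#' @return The treated probability.
#' @export
treated_probability <- function(p_untreated, rrr_per_cycle) {
  if (any(p_untreated < 0 | p_untreated > 1)) stop("p must be in [0,1]")
  out <- p_untreated * (1 - rrr_per_cycle)
  if (any(out > 1)) {
    warning("treated probability clipped to 1")
    out <- pmin(out, 1)
  }
  pmax(out, 0)
}

#' Per-cycle relative risk reductions implied by a parameter set
#'
#' Computes the first- and second-complication per-cycle relative risk
#' reductions from the odds ratios and median treatment durations stored
#' in the parameter set. The baseline annual probability used for the
#' odds conversion is the total (summed over destination states, averaged
#' over sexes) untreated exit probability of the source cluster.
#'
#' @param params A `fabry_params` object.
#' @return A list with elements `first` and `second`.
#' @export
treatment_rrr_per_cycle <- function(params) {
  if (params$or_first == 1 && params$or_second == 1) {
    return(list(first = 0, second = 0))
  }
  tr <- params$transitions
  first_edges <- c("symptoms esrd", "symptoms cardiac", "symptoms cva")
  second_edges <- c("esrd esrd_cardiac", "esrd esrd_cva",
                    "cardiac esrd_cardiac", "cardiac cardiac_cva",
                    "cva esrd_cva", "cva cardiac_cva")
  key <- paste(tr$from, tr$to)
  p_first <- mean(vapply(c("male", "female"), function(sx) {
    sum(tr$p[key %in% first_edges & tr$sex == sx])
  }, numeric(1)))
  second_by_state <- vapply(c("esrd", "cardiac", "cva"), function(s) {
    mean(vapply(c("male", "female"), function(sx) {
      sum(tr$p[tr$from == s & tr$sex == sx & key %in% second_edges])
    }, numeric(1)))
  }, numeric(1))
  p_second <- mean(second_by_state)
  one <- function(p, or, d) {
    if (or == 1 || p <= 0) return(0)
    per_cycle_rrr(p, rrr_over_duration(p, or, d), d)
  }
  list(first = one(p_first, params$or_first,
                   params$median_duration[["symptoms"]]),
       second = one(p_second, params$or_second,
                    params$median_duration[["single_complication"]]))
}
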