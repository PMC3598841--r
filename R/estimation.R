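#' Kaplan-Meier median time-to-event
#'
#' Product-limit median: the first time at which the Kaplan-Meier survival
#' estimate drops to 0.5 or below. If survival never reaches 0.5 (sparse
#' transitions), the time of the last observed event is returned instead
#' and flagged, mirroring the "median or less if 50% was not reached"
#' convention.
#'
#' @param times Positive times to event or censoring (years).
#' @param events Event indicators (1/TRUE = event, 0/FALSE = censored).
#' @return A list with `median` (years), `reached` (logical) and the
#'   underlying `survfit` object.
#' @export
km_median <- function(times, events) {
  events <- as.integer(as.logical(events))
  if (any(times <= 0)) stop("times must be > 0")
  if (sum(events) == 0) stop("median undefined: no events observed")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  drop_idx <- which(fit$surv <= 0.5 + 1e-12)
  if (length(drop_idx)) {
    list(median = fit$time[min(drop_idx)], reached = TRUE, fit = fit)
  } else {
    list(median = max(times[events == 1]), reached = FALSE, fit = fit)
  }
}

#' Annual transition probability from a median time-to-event
#'
#' Under a constant hazard, a median sojourn of `m` years implies a hazard
#' `log(2)/m` and hence a per-cycle transition probability
#' `1 - 2^(-cycle_length/m)`. A one-year median maps to exactly 0.5.
#'
#' @param median Median time in years (> 0).
#' @param cycle_length Model cycle length in years (default 1).
#' @return Annual (per-cycle) transition probability.
#' @export
annual_probability_from_median <- function(median, cycle_length = 1) {
  if (any(median <= 0)) stop("median must be > 0")
  1 - 2^(-cycle_length / median)
}

# inverse: median implied by an annual probability under constant hazard
median_from_annual_probability <- function(p, cycle_length = 1) {
  -cycle_length * log(2) / log(1 - p)
}

#' Mean health utility per disease-state cluster
#'
#' EQ-5D profiles gathered quarterly are converted to utilities with a
#' time-trade-off tariff, averaged per patient per disease-state cluster
#' first, and then per cluster over patients (two-stage averaging, so that
#' patients with many questionnaires do not dominate). Confidence
#' intervals are obtained by a percentile bootstrap that resamples
#' patients.
#'
#' @param records Data frame with columns `patient_id`, `quarter`, `state`,
#'   `MO`, `SC`, `UA`, `PD`, `AD`.
#' @param tariff An `eq5d_tariff` (see [read_tariff()]).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional RNG seed for the bootstrap.
#' @return Data frame with one row per cluster: `cluster`, `n` (patients),
#'   `mean`, `lcl`, `ucl`. Clusters with no records are absent (flagged
#'   missing, never imputed as zero).
#' @export
mean_utility_by_cluster <- function(records, tariff, n_boot = 1000,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- vapply(seq_len(nrow(records)), function(i) {
    eq5d_utility(as.integer(records[i, c("MO", "SC", "UA", "PD", "AD")]),
                 tariff)
  }, numeric(1))
  cl <- state_cluster(records$state)
  df <- data.frame(patient_id = records$patient_id, cluster = cl, u = u,
                   stringsAsFactors = FALSE)
  two_stage <- function(d) {
    per_pat <- tapply(d$u, d$patient_id, mean)
    mean(per_pat)
  }
  out <- do.call(rbind, lapply(split(df, df$cluster), function(d) {
    pats <- unique(d$patient_id)
    boot <- vapply(seq_len(n_boot), function(b) {
      take <- sample(pats, length(pats), replace = TRUE)
      # resample patients; repeated patients contribute repeatedly
      two_stage(do.call(rbind, lapply(take, function(pt) d[d$patient_id == pt, ])))
    }, numeric(1))
    data.frame(cluster = d$cluster[1], n = length(pats), mean = two_stage(d),
               lcl = unname(stats::quantile(boot, 0.025)),
               ucl = unname(stats::quantile(boot, 0.975)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Mean annual medical cost per disease-state cluster
#'
#' Quarterly resource-use counts are costed with a unit-cost table,
#' multiplied by four to give annual figures, averaged per patient per
#' cluster and then per cluster over patients.
#'
#' @param records Data frame with columns `patient_id`, `quarter`, `state`
#'   and one count column per resource category.
#' @param unit_costs Named numeric vector: euro per unit for each resource
#'   category appearing in `records`.
#' @return Data frame `cluster`, `n`, `mean_annual_cost` (euro/year).
#' @export
mean_annual_cost_by_cluster <- function(records, unit_costs) {
  cat_cols <- setdiff(names(records),
                      c("patient_id", "quarter", "state",
                        "sick_days_fortnight", "hours_per_day",
                        "days_per_week", "employment"))
  unknown <- setdiff(cat_cols, names(unit_costs))
  if (length(unknown)) {
    stop("unknown resource categor",
         if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "))
  }
  if (any(as.matrix(records[cat_cols]) < 0)) stop("counts must be >= 0")
  qcost <- as.matrix(records[cat_cols]) %*% unit_costs[cat_cols]
  df <- data.frame(patient_id = records$patient_id,
                   cluster = state_cluster(records$state),
                   annual = 4 * as.numeric(qcost), stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(df, df$cluster), function(d) {
    per_pat <- tapply(d$annual, d$patient_id, mean)
    data.frame(cluster = d$cluster[1], n = length(per_pat),
               mean_annual_cost = mean(per_pat), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Annual productivity loss per disease-state cluster
#'
#' Sick leave is recorded as days per fortnight; annual production loss is
#' days/fortnight x 26 fortnights x mean hours per working day x the unit
#' cost of one production hour. Patients on permanent sick leave because
#' of Fabry disease are assigned a full-time-equivalent annual loss
#' (52 weeks x days/week x hours/day x unit cost); patients without paid
#' work for other reasons contribute zero.
#'
#' @param records Data frame with columns `patient_id`, `quarter`, `state`,
#'   `sick_days_fortnight`, `hours_per_day`, `days_per_week`,
#'   `employment` (one of `"employed"`, `"permanent_sick_leave"`,
#'   `"not_employed_other"`).
#' @param unit_cost_hour Euro per hour of lost production (default 30).
#' @return Data frame `cluster`, `n`, `mean_annual_loss` (euro/year).
#' @export
annual_production_loss <- function(records, unit_cost_hour = 30) {
  if (any(records$sick_days_fortnight < 0, na.rm = TRUE)) {
    stop("sick leave days must be >= 0")
  }
  emp <- records$employment
  hours_day <- mean(records$hours_per_day[emp == "employed"], na.rm = TRUE)
  loss <- numeric(nrow(records))
  i_emp <- emp == "employed"
  loss[i_emp] <- records$sick_days_fortnight[i_emp] * 26 * hours_day *
    unit_cost_hour
  i_perm <- emp == "permanent_sick_leave"
  loss[i_perm] <- 52 * records$days_per_week[i_perm] *
    records$hours_per_day[i_perm] * unit_cost_hour
  df <- data.frame(patient_id = records$patient_id,
                   cluster = state_cluster(records$state),
                   loss = loss, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(df, df$cluster), function(d) {
    per_pat <- tapply(d$loss, d$patient_id, mean)
    data.frame(cluster = d$cluster[1], n = length(per_pat),
               mean_annual_loss = mean(per_pat), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Percentile-bootstrap confidence interval with beta shape parameters
#'
#' Summarises a sample of probabilities by its mean, a 2.5/97.5 percentile
#' bootstrap interval, and the method-of-moments beta shape parameters
#' implied by the bootstrap mean and variance (for second-order draws in
#' the probabilistic sensitivity analysis). A zero-variance sample is
#' flagged degenerate and treated as a point mass.
#'
#' @param observations Values in \[0,1\].
#' @param n_boot Bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @return List with `mean`, `lcl`, `ucl`, `alpha`, `beta`, `degenerate`.
#' @export
bootstrap_beta_ci <- function(observations, n_boot = 1000, seed = NULL) {
  if (any(observations < 0 | observations > 1)) {
    stop("observations must be in [0,1]")
  }
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  m <- mean(observations)
  if (stats::var(observations) == 0 || length(observations) == 1L) {
    return(list(mean = m, lcl = m, ucl = m, alpha = NA_real_,
                beta = NA_real_, degenerate = TRUE))
  }
  boot <- vapply(seq_len(n_boot), function(b) {
    mean(sample(observations, length(observations), replace = TRUE))
  }, numeric(1))
  v <- stats::var(boot)
  shapes <- beta_shapes_mom(m, v)
  list(mean = m,
       lcl = unname(stats::quantile(boot, 0.025)),
       ucl = unname(stats::quantile(boot, 0.975)),
       alpha = shapes$alpha, beta = shapes$beta, degenerate = FALSE)
}

# method-of-moments beta shapes from a mean and variance
beta_shapes_mom <- function(m, v) {
  if (v <= 0 || m <= 0 || m >= 1) return(list(alpha = NA_real_, beta = NA_real_))
  k <- m * (1 - m) / v - 1
  if (k <= 0) return(list(alpha = NA_real_, beta = NA_real_))
  list(alpha = m * k, beta = (1 - m) * k)
}

#' Estimate annual transition probabilities from event histories
#'
#' For every allowed progression edge, the sojourn times in the source
#' state are analysed by Kaplan-Meier survival analysis with transitions
#' to other destinations treated as censoring; the (possibly unreached)
#' median is converted to an annual probability under a constant hazard.
#'
#' @param histories Data frame with columns `patient_id`, `sex`, `state`,
#'   `entry_age`, `exit_age`, `next_state` (`NA`/empty = censored).
#' @param by_sex Estimate separately per sex (default) or pooled (the
#'   pooled estimate is then reported for both sexes; the mode used is
#'   recorded in the `mode` attribute).
#' @param cycle_length Model cycle length in years.
#' @return Data frame `from`, `to`, `sex`, `median`, `median_reached`,
#'   `n`, `events`, `p` suitable as the `transitions` slot of
#'   [fabry_params()] (death rows included, flagged by `to == "death"`).
#' @export
estimate_transition_probabilities <- function(histories, by_sex = TRUE,
                                              cycle_length = 1) {
  need <- c("patient_id", "sex", "state", "entry_age", "exit_age",
            "next_state")
  if (!all(need %in% names(histories))) {
    stop("histories must have columns ", paste(need, collapse = ", "))
  }
  if (any(histories$exit_age <= histories$entry_age)) {
    stop("entry_age must precede exit_age")
  }
  edges <- rbind(fabry_edges(),
                 data.frame(from = setdiff(state_names(), "death"),
                            to = "death"))
  sexes <- if (by_sex) c("male", "female") else "pooled"
  res <- list()
  for (sx in sexes) {
    h <- if (by_sex) histories[histories$sex == sx, ] else histories
    for (i in seq_len(nrow(edges))) {
      from <- edges$from[i]; to <- edges$to[i]
      spell <- h[h$state == from, ]
      if (!nrow(spell)) next
      times <- spell$exit_age - spell$entry_age
      event <- !is.na(spell$next_state) & spell$next_state != "" &
        spell$next_state == to
      if (!any(event)) next
      km <- km_median(times, event)
      res[[length(res) + 1L]] <- data.frame(
        from = from, to = to, sex = sx, median = km$median,
        median_reached = km$reached, n = nrow(spell), events = sum(event),
        p = annual_probability_from_median(km$median, cycle_length),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (!by_sex && !is.null(out)) {
    out <- do.call(rbind, lapply(c("male", "female"), function(sx) {
      o <- out; o$sex <- sx; o
    }))
  }
  attr(out, "mode") <- if (by_sex) "per-sex" else "pooled"
  out
}
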