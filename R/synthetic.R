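#' Load a synthetic parameter preset
#'
#' Three presets are shipped as versioned JSON parameter files (plus a
#' synthetic general-population life table). They stand in for the
#' unpublished cohort-level source tables and are labelled synthetic:
#' \describe{
#'   \item{base}{calibrated so that the untreated lifetime run lands in
#'     the neighbourhood of the published headline outcomes (untreated
#'     years free of end-organ damage between 50 and 60, QALYs between 44
#'     and 53, incremental lifetime ERT cost near 9.6 million euro).}
#'   \item{classical}{faster disease progression, emulating a cohort
#'     restricted to the classical phenotype.}
#'   \item{null-effect}{as `base` but with both odds ratios set to 1
#'     (no treatment effect).}
#' }
#'
#' @param preset `"base"`, `"classical"` or `"null-effect"`.
#' @param seed Accepted for interface symmetry with the other generators;
#'   preset loading is deterministic and ignores it.
#' @return A validated `fabry_params` object with beta shape parameters.
#' @export
generate_parameter_preset <- function(preset = c("base", "classical",
                                                 "null-effect"),
                                      seed = NULL) {
  preset <- match.arg(preset)
  file <- switch(preset, "base" = "preset_base.json",
                 "classical" = "preset_classical.json",
                 "null-effect" = "preset_null_effect.json")
  lt <- system.file("extdata", "life_table_synthetic.csv",
                    package = "fabrycea", mustWork = TRUE)
  read_fabry_params(system.file("extdata", file, package = "fabrycea",
                                mustWork = TRUE),
                    life_table = lt)
}

#' Synthetic-data generator configuration
#'
#' Collects the ground truth for the patient-level generators: per-edge
#' true median sojourn times (derived from the preset's annual
#' probabilities under the constant-hazard conversion, so that estimation
#' on generated data recovers the preset in expectation), true cluster
#' utility means, resource-use rates and the censoring fraction.
#'
#' @param preset Preset name passed to [generate_parameter_preset()].
#' @param n_patients Number of synthetic patients.
#' @param seed Mandatory RNG seed.
#' @param censoring_rate Expected fraction of state spells that end
#'   censored rather than in an observed transition (default 0.15).
#' @param quarters Questionnaire quarters per patient for the EQ-5D and
#'   resource-use generators (default 4).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(preset = "base", n_patients = 200, seed,
                         censoring_rate = 0.15, quarters = 4) {
  if (missing(seed)) stop("a seed is mandatory")
  params <- generate_parameter_preset(preset)
  tr <- params$transitions
  de <- params$death
  tr <- tr[tr$p > 0, ]
  de <- de[de$state != "all" & de$p > 0, ]
  medians <- rbind(
    data.frame(from = tr$from, to = tr$to, sex = tr$sex,
               median = median_from_annual_probability(tr$p),
               stringsAsFactors = FALSE),
    data.frame(from = de$state, to = "death", sex = de$sex,
               median = median_from_annual_probability(de$p),
               stringsAsFactors = FALSE))
  structure(list(
    preset = preset, params = params, n_patients = n_patients, seed = seed,
    censoring_rate = censoring_rate, quarters = quarters,
    medians = medians,
    utility_means = c(asymptomatic = 0.874, acro_or_symptoms = 0.762,
                      single_complication = 0.744,
                      multiple_complications = 0.584),
    cluster_weights = c(asymptomatic = 19, acro_or_symptoms = 55,
                        single_complication = 18,
                        multiple_complications = 5) / 97,
    # quarterly resource-use rates per cluster (counts/quarter)
    resource_rates = list(
      asymptomatic = c(inpatient_day = 0.05, icu_day = 0, daycare_day = 0.05,
                       outpatient_visit = 0.5, gp_visit = 0.5,
                       physiotherapist_visit = 0, psychologist_visit = 0,
                       social_worker_visit = 0, alternative_healer_visit = 0),
      acro_or_symptoms = c(inpatient_day = 0.3, icu_day = 0.01,
                           daycare_day = 0.2, outpatient_visit = 1.5,
                           gp_visit = 1, physiotherapist_visit = 0.5,
                           psychologist_visit = 0.1,
                           social_worker_visit = 0.05,
                           alternative_healer_visit = 0.2),
      single_complication = c(inpatient_day = 1.5, icu_day = 0.05,
                              daycare_day = 0.5, outpatient_visit = 3,
                              gp_visit = 1.5, physiotherapist_visit = 1,
                              psychologist_visit = 0.2,
                              social_worker_visit = 0.1,
                              alternative_healer_visit = 0.3),
      multiple_complications = c(inpatient_day = 4, icu_day = 0.2,
                                 daycare_day = 1, outpatient_visit = 4,
                                 gp_visit = 2, physiotherapist_visit = 2,
                                 psychologist_visit = 0.3,
                                 social_worker_visit = 0.2,
                                 alternative_healer_visit = 0.5)),
    sick_days_fortnight = c(asymptomatic = 0.1, acro_or_symptoms = 0.6,
                            single_complication = 1.5,
                            multiple_complications = 3),
    p_permanent_sick_leave = c(asymptomatic = 0, acro_or_symptoms = 0.05,
                               single_complication = 0.2,
                               multiple_complications = 0.4),
    p_not_employed_other = 0.1,
    hours_per_day = 8, days_per_week = 5),
    class = "synth_config")
}

#' Generate synthetic event histories
#'
#' Walks each patient through the allowed-transition graph from the
#' asymptomatic state at birth, drawing exponential latent sojourn times
#' for every exit edge (including death) with the configured medians, so
#' that cause-specific Kaplan-Meier analysis recovers the generating
#' medians. Independent exponential censoring truncates spells at the
#' configured expected rate; a censored spell ends the patient's record.
#'
#' @param config A `synth_config`.
#' @return Data frame `patient_id`, `sex`, `state`, `entry_age`,
#'   `exit_age`, `next_state` (`NA` when censored), following the
#'   histories schema of the estimation stage.
#' @export
generate_histories <- function(config) {
  set.seed(config$seed)
  med <- config$medians
  out <- vector("list", config$n_patients)
  max_age <- 110
  for (i in seq_len(config$n_patients)) {
    sex <- if (stats::runif(1) < config$params$sex_mix) "male" else "female"
    state <- "asymptomatic"
    age <- 0
    rows <- list()
    while (state != "death" && age < max_age) {
      m <- med[med$sex == sex & med$from == state, ]
      if (!nrow(m)) break
      rates <- log(2) / m$median
      t_lat <- stats::rexp(nrow(m), rates)
      j <- which.min(t_lat)
      t_exit <- t_lat[j]
      nxt <- m$to[j]
      censored <- FALSE
      if (config$censoring_rate > 0) {
        f <- config$censoring_rate
        t_cens <- stats::rexp(1, f / (1 - f) * sum(rates))
        if (t_cens < t_exit) {
          t_exit <- t_cens
          censored <- TRUE
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = i, sex = sex, state = state, entry_age = age,
        exit_age = age + t_exit,
        next_state = if (censored) NA_character_ else nxt,
        stringsAsFactors = FALSE)
      if (censored) break
      age <- age + t_exit
      state <- nxt
    }
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

# profiles of the EQ-5D-3L, their utilities under a tariff
eq5d_profile_table <- function(tariff) {
  grid <- expand.grid(MO = 1:3, SC = 1:3, UA = 1:3, PD = 1:3, AD = 1:3)
  grid$u <- vapply(seq_len(nrow(grid)), function(i)
    eq5d_utility(as.integer(grid[i, 1:5]), tariff), numeric(1))
  grid
}

#' Generate synthetic quarterly EQ-5D records
#'
#' Assigns each patient to one disease-state cluster (with weights
#' emulating the cohort's cluster sizes) and samples EQ-5D profiles as a
#' two-point mixture of the profiles bracketing the target utility under
#' the shipped tariff, so that the expected tariff-evaluated utility per
#' cluster equals the configured cluster mean exactly.
#'
#' @param config A `synth_config`.
#' @param tariff An `eq5d_tariff` (default: the UK time-trade-off tariff).
#' @return Data frame `patient_id`, `quarter`, `state`, `MO`, `SC`, `UA`,
#'   `PD`, `AD`.
#' @export
generate_eq5d <- function(config, tariff = read_tariff("uk_tto")) {
  set.seed(config$seed + 1)
  prof <- eq5d_profile_table(tariff)
  cluster_states <- list(
    asymptomatic = "asymptomatic",
    acro_or_symptoms = c("acroparesthesia", "symptoms"),
    single_complication = c("esrd", "cardiac", "cva"),
    multiple_complications = c("esrd_cardiac", "esrd_cva", "cardiac_cva",
                               "esrd_cardiac_cva"))
  clusters <- sample(names(config$cluster_weights), config$n_patients,
                     replace = TRUE, prob = config$cluster_weights)
  out <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    cl <- clusters[i]
    target <- config$utility_means[[cl]]
    if (target > max(prof$u) || target < min(prof$u)) {
      stop("target mean utility ", target,
           " unreachable under the tariff support")
    }
    lo <- prof[prof$u <= target, ][which.max(prof$u[prof$u <= target]), ]
    hi <- prof[prof$u >= target, ][which.min(prof$u[prof$u >= target]), ]
    w <- if (hi$u == lo$u) 1 else (target - lo$u) / (hi$u - lo$u)
    st <- sample(cluster_states[[cl]], config$quarters, replace = TRUE)
    pick_hi <- stats::runif(config$quarters) < w
    profs <- rbind(hi[rep(1, config$quarters), 1:5])
    profs[!pick_hi, ] <- lo[rep(1, sum(!pick_hi)), 1:5]
    out[[i]] <- data.frame(patient_id = i,
                           quarter = seq_len(config$quarters),
                           state = st, profs, stringsAsFactors = FALSE,
                           row.names = NULL)
  }
  do.call(rbind, out)
}

#' Generate synthetic quarterly resource-use records
#'
#' Poisson counts per resource category with cluster-specific quarterly
#' rates, plus sick-leave and work-pattern fields following the costing
#' rules (employed with Poisson sick-days per fortnight, permanent sick
#' leave, or not employed for non-disease reasons).
#'
#' @param config A `synth_config`.
#' @return Data frame in the resource-use schema of the estimation stage.
#' @export
generate_resource_use <- function(config) {
  set.seed(config$seed + 2)
  cluster_states <- list(
    asymptomatic = "asymptomatic",
    acro_or_symptoms = c("acroparesthesia", "symptoms"),
    single_complication = c("esrd", "cardiac", "cva"),
    multiple_complications = c("esrd_cardiac", "esrd_cva", "cardiac_cva",
                               "esrd_cardiac_cva"))
  clusters <- sample(names(config$cluster_weights), config$n_patients,
                     replace = TRUE, prob = config$cluster_weights)
  out <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    cl <- clusters[i]
    rates <- config$resource_rates[[cl]]
    q <- config$quarters
    counts <- vapply(rates, function(r) stats::rpois(q, r),
                     numeric(q))
    if (q == 1L) counts <- matrix(counts, nrow = 1,
                                  dimnames = list(NULL, names(rates)))
    u <- stats::runif(1)
    employment <- if (u < config$p_not_employed_other) "not_employed_other"
      else if (u < config$p_not_employed_other +
                 config$p_permanent_sick_leave[[cl]]) "permanent_sick_leave"
      else "employed"
    sick <- if (employment == "employed") {
      stats::rpois(q, config$sick_days_fortnight[[cl]])
    } else rep(0, q)
    out[[i]] <- data.frame(
      patient_id = i, quarter = seq_len(q),
      state = sample(cluster_states[[cl]], q, replace = TRUE),
      counts,
      sick_days_fortnight = sick,
      hours_per_day = config$hours_per_day,
      days_per_week = config$days_per_week,
      employment = employment, stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Unit costs for the resource categories of the synthetic generator
#'
#' Dutch 2009 unit costs (euro) for the out-of-AMC resource categories:
#' inpatient day 457, ICU day 2183, day-care day 251, outpatient visit
#' 72, general practitioner 28, physiotherapist 36,
#' psychiatrist/psychologist 91.5, social worker 65, alternative healer
#' 60.
#'
#' @return Named numeric vector, euro per unit.
#' @export
default_unit_costs <- function() {
  c(inpatient_day = 457, icu_day = 2183, daycare_day = 251,
    outpatient_visit = 72, gp_visit = 28, physiotherapist_visit = 36,
    psychologist_visit = 91.5, social_worker_visit = 65,
    alternative_healer_visit = 60)
}
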