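#' Construct a model parameter set
#'
#' The parameter set collects everything the lifetime model needs: annual
#' state-transition probabilities by sex (with optional 95% confidence
#' limits and beta shape parameters for probabilistic analysis),
#' disease-related annual death probabilities, per-cluster health
#' utilities, per-state annual costs, the annual drug cost of enzyme
#' replacement therapy, per-treatment-year odds ratios for the first and
#' second complication together with the median treatment durations over
#' which they compound, discount rates, the simulation horizon, the sex
#' mix of the cohort, a general-population life table and the
#' willingness-to-pay grid.
#'
#' @param transitions Data frame with columns `from`, `to`, `sex`
#'   (`"male"`/`"female"`), `p` and optionally `lcl`, `ucl`, `alpha`,
#'   `beta`. One row per allowed disease-progression edge and sex
#'   (death rows are supplied via `death`).
#' @param death Data frame with columns `state`, `sex`, `p` and optionally
#'   `lcl`, `ucl`, `alpha`, `beta`, giving the annual disease-related death
#'   probability. `state = "all"` supplies a shared probability for states
#'   without their own row; states without any row fall back to 0 (the
#'   general-population floor still applies).
#' @param utilities Named numeric vector of utilities per year for the
#'   living clusters `asymptomatic`, `acro_or_symptoms`,
#'   `single_complication`, `multiple_complications`. Death counts 0.
#' @param cost_state Named numeric vector of annual costs in euro per
#'   living state (per-state resolution so that e.g. dialysis costs can be
#'   attached to the ESRD states).
#' @param cost_production_loss Named numeric vector of annual productivity
#'   losses in euro per living cluster (used only in the scenario that
#'   adds indirect non-medical costs).
#' @param cost_ert Annual drug cost of enzyme replacement therapy in euro
#'   (about 200,000 for agalsidase alfa/beta at 70 kg).
#' @param unit_cost_hour Unit cost of one hour of lost production (euro).
#' @param or_first,or_second Odds ratios per treatment-year for progression
#'   from symptoms to a first complication (0.82) and from a single to a
#'   second complication (0.52).
#' @param median_duration Named numeric vector with elements `symptoms` and
#'   `single_complication`: median treatment duration (years) in the state,
#'   over which the per-year odds ratio compounds.
#' @param discount_rate_effects,discount_rate_costs Annual discount rates
#'   for effects (0.015 in the differential mode) and costs (0.04).
#' @param horizon Number of one-year cycles (70: birth to age 70).
#' @param cycle_length Cycle length in years (1).
#' @param sex_mix Fraction of males in the cohort (0.5).
#' @param life_table Data frame `age`, `sex`, `qx` with the annual
#'   general-population death probability; must cover ages `0:(horizon-1)`
#'   for both sexes.
#' @param wtp_grid Willingness-to-pay values in euro per QALY.
#' @param ert_start_rule Default treatment strategy descriptor, one of
#'   `"at-symptoms"`, `"at-age-40"`, `"never"`,
#'   `"stop-after-2-complications"`.
#' @return An object of class `fabry_params`.
#' @export
fabry_params <- function(transitions, death, utilities, cost_state,
                         cost_production_loss = NULL,
                         cost_ert = 200000, unit_cost_hour = 30,
                         or_first = 0.82, or_second = 0.52,
                         median_duration = c(symptoms = 5,
                                             single_complication = 5),
                         discount_rate_effects = 0.015,
                         discount_rate_costs = 0.04,
                         horizon = 70, cycle_length = 1, sex_mix = 0.5,
                         life_table = NULL,
                         wtp_grid = default_wtp_grid(),
                         ert_start_rule = "at-symptoms") {
  if (is.null(cost_production_loss)) {
    cost_production_loss <- c(asymptomatic = 0, acro_or_symptoms = 0,
                              single_complication = 0,
                              multiple_complications = 0)
  }
  p <- structure(
    list(transitions = transitions, death = death, utilities = utilities,
         cost_state = cost_state,
         cost_production_loss = cost_production_loss,
         cost_ert = cost_ert, unit_cost_hour = unit_cost_hour,
         or_first = or_first, or_second = or_second,
         median_duration = median_duration,
         discount_rate_effects = discount_rate_effects,
         discount_rate_costs = discount_rate_costs,
         horizon = as.integer(horizon), cycle_length = cycle_length,
         sex_mix = sex_mix, life_table = life_table, wtp_grid = wtp_grid,
         ert_start_rule = ert_start_rule),
    class = "fabry_params")
  validate_params(p)
}

#' Default willingness-to-pay grid
#'
#' 25 log-spaced values from 20,000 to 10,000,000 euro per QALY.
#' @return Numeric vector of willingness-to-pay values (euro per QALY).
#' @export
default_wtp_grid <- function() {
  exp(seq(log(20000), log(1e7), length.out = 25))
}

#' Validate a parameter set
#'
#' Checks all probabilities lie in \[0,1\], costs are non-negative,
#' utilities lie in \[0,1\], odds ratios are positive, every allowed
#' progression edge has an untreated probability for both sexes, and the
#' life table covers ages 0 to horizon-1 for both sexes.
#'
#' @param p A `fabry_params` object.
#' @return `p`, invisibly-checked (errors on violation).
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "fabry_params"))
  tr <- p$transitions
  if (!all(c("from", "to", "sex", "p") %in% names(tr))) {
    stop("transitions must have columns from, to, sex, p")
  }
  if (any(tr$p < 0 | tr$p > 1)) stop("transition probabilities must be in [0,1]")
  edges <- fabry_edges()
  for (sx in c("male", "female")) {
    have <- paste(tr$from[tr$sex == sx], tr$to[tr$sex == sx])
    need <- paste(edges$from, edges$to)
    miss <- setdiff(need, have)
    if (length(miss)) {
      stop("configuration error: missing ", sx, " probability for edge(s): ",
           paste(miss, collapse = "; "))
    }
  }
  bad <- !(paste(tr$from, tr$to) %in% paste(edges$from, edges$to))
  if (any(bad)) {
    stop("transition(s) not in the allowed graph: ",
         paste(unique(paste(tr$from, "->", tr$to)[bad]), collapse = "; "))
  }
  if (any(p$death$p < 0 | p$death$p > 1)) stop("death probabilities must be in [0,1]")
  cl_need <- c("asymptomatic", "acro_or_symptoms", "single_complication",
               "multiple_complications")
  if (!all(cl_need %in% names(p$utilities))) {
    stop("utilities must be named for clusters: ",
         paste(cl_need, collapse = ", "))
  }
  if (any(p$utilities < 0 | p$utilities > 1)) stop("utilities must be in [0,1]")
  living <- setdiff(state_names(), "death")
  if (!all(living %in% names(p$cost_state))) {
    stop("cost_state must cover all living states")
  }
  if (any(p$cost_state < 0) || p$cost_ert < 0 ||
      any(p$cost_production_loss < 0)) {
    stop("costs must be non-negative")
  }
  if (p$or_first <= 0 || p$or_second <= 0) stop("odds ratios must be > 0")
  if (any(p$median_duration <= 0)) stop("median treatment durations must be > 0")
  if (is.null(p$life_table)) stop("a life table is required")
  lt <- p$life_table
  if (!all(c("age", "sex", "qx") %in% names(lt))) {
    stop("life table must have columns age, sex, qx")
  }
  if (any(lt$qx < 0 | lt$qx > 1)) stop("life-table qx must be in [0,1]")
  for (sx in c("male", "female")) {
    ages <- lt$age[lt$sex == sx]
    if (!all(0:(p$horizon - 1) %in% ages)) {
      stop("life table must cover ages 0..", p$horizon - 1, " for ", sx)
    }
  }
  if (p$sex_mix < 0 || p$sex_mix > 1) stop("sex_mix must be in [0,1]")
  if (!p$ert_start_rule %in% c("at-symptoms", "at-age-40", "never",
                               "stop-after-2-complications")) {
    stop("unknown ert_start_rule: ", p$ert_start_rule)
  }
  p
}

#' @export
print.fabry_params <- function(x, ...) {
  cat("Fabry disease model parameter set\n")
  cat("  transitions:", nrow(x$transitions), "edge probabilities;",
      "horizon:", x$horizon, "one-year cycles\n")
  cat("  ERT cost/yr: ", format(x$cost_ert, big.mark = ","),
      "; OR first/second complication: ", x$or_first, "/", x$or_second, "\n",
      sep = "")
  cat("  discounting: effects ", 100 * x$discount_rate_effects,
      "%, costs ", 100 * x$discount_rate_costs, "%\n", sep = "")
  invisible(x)
}

#' General-population mortality floor
#'
#' The annual probability of dying in the model is never allowed to fall
#' below the probability for the general population of the same age and
#' sex (taken from a national life table): the floor is the maximum of the
#' model probability and the life-table probability.
#'
#' @param p_model Model (disease-related) annual death probability.
#' @param age Age in whole years.
#' @param sex `"male"` or `"female"`.
#' @param life_table Data frame `age`, `sex`, `qx`.
#' @return The floored probability.
#' @export
apply_mortality_floor <- function(p_model, age, sex, life_table) {
  if (any(p_model < 0 | p_model > 1)) stop("p_model must be in [0,1]")
  q <- lt_qx(life_table, age, sex)
  pmax(p_model, q)
}

lt_qx <- function(life_table, age, sex) {
  i <- which(life_table$age == age & life_table$sex == sex)
  if (!length(i)) stop("age ", age, " (", sex, ") outside the life table")
  life_table$qx[i[1]]
}

#' Read a life table
#'
#' @param path Delimited text file with header `age,sex,qx`.
#' @return Data frame with columns `age`, `sex`, `qx`.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "sex", "qx") %in% names(lt))) {
    stop("life table must have header age,sex,qx")
  }
  if (any(lt$qx < 0 | lt$qx > 1)) stop("qx must be in [0,1]")
  lt
}

# disease-related death probability for one state/sex, before the floor
death_p_state <- function(params, state, sex) {
  d <- params$death
  i <- which(d$state == state & d$sex %in% c(sex, "both"))
  if (length(i)) return(d$p[i[1]])
  i <- which(d$state == "all" & d$sex %in% c(sex, "both"))
  if (length(i)) return(d$p[i[1]])
  0
}

#' Assemble the annual transition matrix
#'
#' Builds the row-stochastic 11x11 one-cycle transition matrix for a given
#' sex, treatment status and age. Listed progression probabilities fill the
#' off-diagonal entries; the death entry is the disease-related death
#' probability floored by the general-population life table at the given
#' age; all residual probability stays on the diagonal. Under treatment,
#' the three symptoms-to-first-complication probabilities are multiplied by
#' one minus the per-cycle relative risk reduction implied by the
#' first-complication odds ratio, and the single-to-double-complication
#' probabilities by the second-complication analogue.
#'
#' @param params A `fabry_params` object.
#' @param sex `"male"` or `"female"`.
#' @param treated Logical: either a scalar (all states share treatment
#'   status) or a named logical vector over states, as produced by a
#'   treatment strategy.
#' @param age Age in whole years at the start of the cycle.
#' @return An 11x11 row-stochastic matrix with dimnames `state_names()`.
#' @export
build_transition_matrix <- function(params, sex, treated, age,
                                    .prep = NULL) {
  sn <- state_names()
  n <- length(sn)
  if (length(treated) == 1L) treated <- stats::setNames(rep(treated, n), sn)
  prep <- if (is.null(.prep)) engine_prep(params) else .prep
  px <- prep[[sex]]
  fac <- rep(1, length(px$p))
  on <- treated[px$from_idx]
  fac[px$is_first & on] <- 1 - prep$rrr$first
  fac[px$is_second & on] <- 1 - prep$rrr$second
  pa <- px$p * fac
  M <- matrix(0, n, n, dimnames = list(sn, sn))
  M[cbind(px$from_idx, px$to_idx)] <- pa
  age_i <- match(age, prep$ages)
  if (is.na(age_i)) stop("age ", age, " outside the life table")
  p_death <- pmax(px$death_p, px$qx[age_i])
  M[seq_len(n - 1L), n] <- p_death
  exit_sum <- rowSums(M)[seq_len(n - 1L)]
  if (any(exit_sum > 1 + 1e-12)) {
    bad <- sn[which(exit_sum > 1 + 1e-12)[1]]
    stop("parameter error: exit probabilities from '", bad,
         "' exceed 1 at age ", age)
  }
  diag(M)[seq_len(n - 1L)] <- diag(M)[seq_len(n - 1L)] +
    pmax(1 - exit_sum, 0)
  M[n, n] <- 1
  M
}

# Precompute the per-sex transition template, death probabilities,
# life-table columns and treatment-effect reductions for fast repeated
# matrix assembly (cohort cycles, microsimulation, PSA draws).
engine_prep <- function(params) {
  sn <- state_names()
  n_living <- length(sn) - 1L
  first_edges <- paste("symptoms", c("esrd", "cardiac", "cva"))
  second_edges <- c("esrd esrd_cardiac", "esrd esrd_cva",
                    "cardiac esrd_cardiac", "cardiac cardiac_cva",
                    "cva esrd_cva", "cva cardiac_cva")
  ages <- (seq_len(params$horizon) - 1L) * params$cycle_length
  out <- list(rrr = treatment_rrr_per_cycle(params), ages = ages)
  for (sx in c("male", "female")) {
    tr <- params$transitions[params$transitions$sex == sx, ]
    key <- paste(tr$from, tr$to)
    lt <- params$life_table[params$life_table$sex == sx, ]
    out[[sx]] <- list(
      from_idx = match(tr$from, sn),
      to_idx = match(tr$to, sn),
      p = tr$p,
      is_first = key %in% first_edges,
      is_second = key %in% second_edges,
      death_p = vapply(sn[seq_len(n_living)], function(s)
        death_p_state(params, s, sx), numeric(1)),
      qx = lt$qx[match(ages, lt$age)])
  }
  out
}
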