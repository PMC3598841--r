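#' Treatment strategies
#'
#' A strategy is a predicate mapping (state, age) to a treatment flag:
#' \describe{
#'   \item{no_ert}{never treated (standard medical care).}
#'   \item{ert_at_symptoms}{ERT from the moment symptoms develop: the
#'     symptomatic state and every complication state are treated, at any
#'     age. Asymptomatic and acroparesthesia states are untreated (no
#'     indication yet); transplant returnees to the symptomatic state are
#'     treated again.}
#'   \item{ert_at_40}{as `ert_at_symptoms`, but not before age 40.}
#'   \item{ert_stop_after_2}{as `ert_at_symptoms`, but treatment stops
#'     once a second complication is gained: double and triple complication
#'     states accrue no drug cost and no treatment effect.}
#' }
#' Death is never treated.
#'
#' @param name One of `"no_ert"`, `"ert_at_symptoms"`, `"ert_at_40"`,
#'   `"ert_stop_after_2"`.
#' @return An object of class `ert_strategy` with elements `name` and
#'   `treated(age)`, returning a named logical vector over states.
#' @export
ert_strategy <- function(name = c("no_ert", "ert_at_symptoms", "ert_at_40",
                                  "ert_stop_after_2")) {
  name <- match.arg(name)
  st <- fabry_states()
  never <- stats::setNames(rep(FALSE, nrow(st)), st$name)
  from_symptoms <- never
  from_symptoms[!is.na(st$complication_count) &
                  (st$name == "symptoms" | st$complication_count >= 1)] <- TRUE
  upto_single <- from_symptoms
  upto_single[st$name[!is.na(st$complication_count) &
                        st$complication_count >= 2]] <- FALSE
  treated <- switch(name,
    no_ert = function(age) never,
    ert_at_symptoms = function(age) from_symptoms,
    ert_at_40 = function(age) if (age >= 40) from_symptoms else never,
    ert_stop_after_2 = function(age) upto_single)
  structure(list(name = name, treated = treated), class = "ert_strategy")
}

# map a parameter-file start rule to a strategy
strategy_from_rule <- function(rule) {
  ert_strategy(switch(rule,
    "at-symptoms" = "ert_at_symptoms",
    "at-age-40" = "ert_at_40",
    "never" = "no_ert",
    "stop-after-2-complications" = "ert_stop_after_2",
    stop("unknown ert_start_rule: ", rule)))
}

#' Discount factor
#'
#' `1/(1+rate)^cycle_index`, with cycle index 0 for the first model year
#' (the first cycle is undiscounted).
#'
#' @param rate Annual discount rate (>= 0).
#' @param cycle_index 0-based cycle index.
#' @return The discount factor.
#' @export
discount_factor <- function(rate, cycle_index) {
  if (any(rate < 0)) stop("rate must be >= 0")
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0")
  1 / (1 + rate)^cycle_index
}

#' Run the deterministic cohort model for one sex
#'
#' Advances a cohort that starts fully asymptomatic at birth through
#' `horizon` one-year cycles. Each cycle assembles the age- and
#' treatment-dependent transition matrix, advances the occupancy vector,
#' and accrues outcomes from the post-transition occupancy (no half-cycle
#' correction). The ERT drug cost accrues only for alive occupancy in
#' treated states.
#'
#' @param params A `fabry_params` object.
#' @param strategy An `ert_strategy` (or its name).
#' @param sex `"male"` or `"female"`.
#' @return A `fabry_trace`: list with the post-transition `occupancy`
#'   matrix (cycles x states), `treated` logical matrix, `ages`, `sex`,
#'   `strategy`, `params` bookkeeping fields.
#' @export
run_cohort <- function(params, strategy, sex) {
  if (is.character(strategy)) strategy <- ert_strategy(strategy)
  sn <- state_names()
  h <- params$horizon
  occ <- stats::setNames(rep(0, length(sn)), sn)
  occ["asymptomatic"] <- 1
  occupancy <- matrix(NA_real_, h, length(sn), dimnames = list(NULL, sn))
  treated_m <- matrix(FALSE, h, length(sn), dimnames = list(NULL, sn))
  prep <- engine_prep(params)
  for (t in seq_len(h) - 1L) {
    age <- t * params$cycle_length
    treated <- strategy$treated(age)
    M <- build_transition_matrix(params, sex, treated, age, .prep = prep)
    if (any(abs(rowSums(M) - 1) > 1e-12)) {
      stop("non-stochastic transition matrix at cycle ", t)
    }
    occ <- as.numeric(occ %*% M)
    names(occ) <- sn
    occupancy[t + 1L, ] <- occ
    treated_m[t + 1L, ] <- treated
  }
  structure(list(occupancy = occupancy, treated = treated_m,
                 ages = (seq_len(h) - 1L) * params$cycle_length,
                 sex = sex, strategy = strategy$name,
                 cycle_length = params$cycle_length),
            class = "fabry_trace")
}

#' @export
print.fabry_trace <- function(x, ...) {
  cat("Cohort trace:", nrow(x$occupancy), "cycles,", x$sex,
      ", strategy", x$strategy, "\n")
  cat("  surviving fraction at horizon:",
      round(1 - x$occupancy[nrow(x$occupancy), "death"], 3), "\n")
  invisible(x)
}

trace_discount <- function(trace, rate) {
  discount_factor(rate, seq_len(nrow(trace$occupancy)) - 1L)
}

#' Accrued life-years of a cohort trace
#'
#' @param trace A `fabry_trace`.
#' @param rate Annual discount rate for effects (default 0).
#' @return Life-years per cohort member.
#' @export
accrue_life_years <- function(trace, rate = 0) {
  alive <- 1 - trace$occupancy[, "death"]
  sum(alive * trace_discount(trace, rate)) * trace$cycle_length
}

#' Accrued years free of end-organ damage
#'
#' Years spent in the asymptomatic, acroparesthesia or symptomatic states.
#'
#' @param trace A `fabry_trace`.
#' @param rate Annual discount rate for effects (default 0).
#' @return YFEOD per cohort member.
#' @export
accrue_yfeod <- function(trace, rate = 0) {
  free <- rowSums(trace$occupancy[, yfeod_states(), drop = FALSE])
  sum(free * trace_discount(trace, rate)) * trace$cycle_length
}

#' Accrued quality-adjusted life-years
#'
#' Occupancy weighted by the per-cluster utility; with a one-year cycle
#' the mean utility in a cycle is the QALY yield of that cycle. Death
#' contributes zero.
#'
#' @param trace A `fabry_trace`.
#' @param utilities Named utility vector per living cluster.
#' @param rate Annual discount rate for effects (default 0).
#' @return QALYs per cohort member.
#' @export
accrue_qalys <- function(trace, utilities, rate = 0) {
  living <- setdiff(state_names(), "death")
  cl <- state_cluster(living)
  if (!all(cl %in% names(utilities))) {
    stop("missing utility for cluster(s): ",
         paste(setdiff(cl, names(utilities)), collapse = ", "))
  }
  u_state <- utilities[cl]
  per_cycle <- as.numeric(trace$occupancy[, living, drop = FALSE] %*% u_state)
  sum(per_cycle * trace_discount(trace, rate)) * trace$cycle_length
}

#' Accrued costs of a cohort trace
#'
#' Annual state costs weighted by occupancy, plus the ERT drug cost for
#' alive occupancy in treated states, plus (optionally) productivity
#' losses for cycles at age 18 and over.
#'
#' @param trace A `fabry_trace`.
#' @param params A `fabry_params` object.
#' @param rate Annual discount rate for costs (default 0).
#' @param production_loss Include indirect non-medical costs of production
#'   loss (scenario analysis; default `FALSE`).
#' @return A list with `total`, `state`, `ert`, `production` (euro).
#' @export
accrue_costs <- function(trace, params, rate = 0, production_loss = FALSE) {
  if (any(params$cost_state < 0)) stop("costs must be non-negative")
  living <- setdiff(state_names(), "death")
  disc <- trace_discount(trace, rate)
  occ <- trace$occupancy[, living, drop = FALSE]
  c_state <- sum(as.numeric(occ %*% params$cost_state[living]) * disc)
  treated_occ <- rowSums(occ * trace$treated[, living, drop = FALSE])
  c_ert <- params$cost_ert * sum(treated_occ * disc)
  c_prod <- 0
  if (production_loss) {
    loss_state <- params$cost_production_loss[state_cluster(living)]
    eligible <- trace$ages + trace$cycle_length >= 18
    c_prod <- sum(as.numeric(occ %*% loss_state) * disc * eligible)
  }
  c_state <- c_state * trace$cycle_length
  c_ert <- c_ert * trace$cycle_length
  c_prod <- c_prod * trace$cycle_length
  list(total = c_state + c_ert + c_prod, state = c_state, ert = c_ert,
       production = c_prod)
}

#' Export a cohort trace as a per-cycle table
#'
#' @param x A `fabry_trace`.
#' @param ... Unused.
#' @return Data frame: one row per cycle with age, state occupancies and
#'   the alive/treated fractions.
#' @export
as.data.frame.fabry_trace <- function(x, ...) {
  d <- as.data.frame(x$occupancy)
  data.frame(cycle = seq_len(nrow(d)) - 1L, age = x$ages, d,
             alive = 1 - d$death,
             treated = rowSums(x$occupancy * x$treated))
}

#' Individual-level microsimulation
#'
#' Simulates `n_patients` individual trajectories through the model:
#' each patient draws a sex according to the sex mix and then a state path
#' by categorical sampling from the same per-cycle transition matrices
#' that drive the cohort model. Mean outcomes converge to the cohort
#' expectation as the number of patients grows.
#'
#' @param params A `fabry_params` object.
#' @param strategy An `ert_strategy` or its name.
#' @param n_patients Number of simulated patients.
#' @param seed RNG seed (`NULL` to use the current RNG stream; supply an
#'   integer for reproducibility).
#' @param sex_mix Fraction male (defaults to `params$sex_mix`).
#' @param production_loss Include productivity losses in costs.
#' @return A list with `outcomes` (per-patient data frame: sex, life-years,
#'   YFEOD, QALYs, costs, discounted and undiscounted) and `mean` (named
#'   vector of the column means of the numeric outcomes).
#' @export
run_microsim <- function(params, strategy, n_patients, seed = NULL,
                         sex_mix = params$sex_mix, production_loss = FALSE) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (is.character(strategy)) strategy <- ert_strategy(strategy)
  if (!is.null(seed)) set.seed(seed)
  sn <- state_names()
  h <- params$horizon
  n <- as.integer(n_patients)
  sex <- ifelse(stats::runif(n) < sex_mix, "male", "female")
  re <- params$discount_rate_effects
  rc <- params$discount_rate_costs
  living <- setdiff(sn, "death")
  u_state <- stats::setNames(c(params$utilities[state_cluster(living)], 0),
                             sn)
  cost_state <- stats::setNames(c(params$cost_state[living], 0), sn)
  loss_state <- stats::setNames(
    c(params$cost_production_loss[state_cluster(living)], 0), sn)
  yf <- stats::setNames(as.numeric(sn %in% yfeod_states()), sn)
  acc <- matrix(0, n, 10,
                dimnames = list(NULL, c("ly", "yfeod", "qalys", "cost",
                                        "cost_ert", "ly_disc", "yfeod_disc",
                                        "qalys_disc", "cost_disc",
                                        "cost_ert_disc")))
  state <- rep(1L, n)  # asymptomatic
  death_i <- match("death", sn)
  prep <- engine_prep(params)
  for (t in seq_len(h) - 1L) {
    age <- t * params$cycle_length
    treated <- strategy$treated(age)
    fe <- discount_factor(re, t)
    fc <- discount_factor(rc, t)
    new_state <- state
    for (sx in c("male", "female")) {
      M <- NULL
      for (s in which(tabulate(state[sex == sx], length(sn)) > 0)) {
        if (s == death_i) next
        if (is.null(M)) {
          M <- build_transition_matrix(params, sx, treated, age,
                                       .prep = prep)
        }
        idx <- which(sex == sx & state == s)
        new_state[idx] <- sample.int(length(sn), length(idx),
                                     replace = TRUE, prob = M[s, ])
      }
    }
    state <- new_state
    st_name <- sn[state]
    alive <- state != death_i
    on_ert <- alive & treated[st_name]
    u <- u_state[st_name]
    cst <- cost_state[st_name]
    if (production_loss && (age + params$cycle_length >= 18)) {
      cst <- cst + loss_state[st_name]
    }
    drug <- ifelse(on_ert, params$cost_ert, 0)
    cl <- params$cycle_length
    acc[, "ly"] <- acc[, "ly"] + alive * cl
    acc[, "yfeod"] <- acc[, "yfeod"] + yf[st_name] * cl
    acc[, "qalys"] <- acc[, "qalys"] + u * cl
    acc[, "cost"] <- acc[, "cost"] + (cst + drug) * cl
    acc[, "cost_ert"] <- acc[, "cost_ert"] + drug * cl
    acc[, "ly_disc"] <- acc[, "ly_disc"] + alive * fe * cl
    acc[, "yfeod_disc"] <- acc[, "yfeod_disc"] + yf[st_name] * fe * cl
    acc[, "qalys_disc"] <- acc[, "qalys_disc"] + u * fe * cl
    acc[, "cost_disc"] <- acc[, "cost_disc"] + (cst + drug) * fc * cl
    acc[, "cost_ert_disc"] <- acc[, "cost_ert_disc"] + drug * fc * cl
  }
  outcomes <- data.frame(sex = sex, acc)
  list(outcomes = outcomes, mean = colMeans(acc))
}
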