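# minimal valid parameter sets for engine unit tests

flat_life_table <- function(qx = 0, horizon = 70) {
  ages <- 0:(horizon - 1)
  rbind(data.frame(age = ages, sex = "male", qx = qx),
        data.frame(age = ages, sex = "female", qx = qx))
}

# all progression edges present with probability 0 unless overridden;
# a single shared death probability; flat life table
toy_params <- function(p_edges = NULL, p_death = 0, qx = 0,
                       utilities = c(asymptomatic = 1,
                                     acro_or_symptoms = 1,
                                     single_complication = 1,
                                     multiple_complications = 1),
                       cost_state = NULL, cost_ert = 200000,
                       or_first = 1, or_second = 1,
                       median_duration = c(symptoms = 1,
                                           single_complication = 1),
                       horizon = 70) {
  edges <- fabry_edges()
  tr <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    data.frame(from = edges$from, to = edges$to, sex = sx, p = 0)
  }))
  if (!is.null(p_edges)) {
    for (k in seq_len(nrow(p_edges))) {
      i <- tr$from == p_edges$from[k] & tr$to == p_edges$to[k]
      tr$p[i] <- p_edges$p[k]
    }
  }
  de <- rbind(data.frame(state = "all", sex = "male", p = p_death),
              data.frame(state = "all", sex = "female", p = p_death))
  if (is.null(cost_state)) {
    cost_state <- setNames(rep(0, 10), setdiff(state_names(), "death"))
  }
  fabry_params(transitions = tr, death = de, utilities = utilities,
               cost_state = cost_state, cost_ert = cost_ert,
               or_first = or_first, or_second = or_second,
               median_duration = median_duration,
               life_table = flat_life_table(qx, horizon),
               horizon = horizon)
}

# hand-built trace for accrual tests: full mass in one state (or a named
# occupancy vector), optionally all treated
manual_trace <- function(occ, cycles, treated = FALSE) {
  sn <- state_names()
  if (is.character(occ)) {
    v <- setNames(rep(0, length(sn)), sn)
    v[occ] <- 1
    occ <- v
  }
  structure(list(
    occupancy = matrix(rep(occ, each = cycles), cycles, length(sn),
                       dimnames = list(NULL, sn)),
    treated = matrix(treated, cycles, length(sn),
                     dimnames = list(NULL, sn)),
    ages = 0:(cycles - 1), sex = "male", strategy = "manual",
    cycle_length = 1), class = "fabry_trace")
}
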