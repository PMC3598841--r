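#' Read a model parameter file
#'
#' Parameter files are JSON with sections `states`, `transitions`,
#' `death`, `utilities`, `costs`, `treatment_effect`, `discounting` and
#' `simulation`; the shipped schema (`params_schema.json`) is validated on
#' load. Transition and death rows may carry 95% confidence limits
#' (`lcl`, `ucl`); when beta shape parameters are absent they are derived
#' from the limits by method of moments (interval width / 3.92 as the
#' standard deviation), so that the file is immediately usable in the
#' probabilistic sensitivity analysis.
#'
#' @param path Path to the JSON parameter file.
#' @param life_table A life-table data frame or the path to a
#'   `age,sex,qx` file; required unless the JSON carries a `life_table`
#'   section.
#' @return A validated `fabry_params` object.
#' @export
read_fabry_params <- function(path, life_table = NULL) {
  obj <- jsonlite::fromJSON(path)
  validate_params_schema(obj)
  if (is.character(life_table)) life_table <- read_life_table(life_table)
  if (is.null(life_table)) {
    if (is.null(obj$life_table)) stop("no life table supplied")
    life_table <- as.data.frame(obj$life_table)
  }
  tr <- add_beta_shapes(as.data.frame(obj$transitions))
  de <- add_beta_shapes(as.data.frame(obj$death))
  sim <- obj$simulation
  wtp <- if (is.null(sim$wtp_grid)) default_wtp_grid() else
    as.numeric(sim$wtp_grid)
  p <- fabry_params(
    transitions = tr, death = de,
    utilities = unlist(obj$utilities),
    cost_state = unlist(obj$costs$state),
    cost_production_loss = if (is.null(obj$costs$production_loss)) NULL
      else unlist(obj$costs$production_loss),
    cost_ert = obj$costs$ert_per_year,
    unit_cost_hour = obj$costs$unit_cost_hour,
    or_first = obj$treatment_effect$or_first,
    or_second = obj$treatment_effect$or_second,
    median_duration = c(
      symptoms = obj$treatment_effect$median_duration_symptoms,
      single_complication =
        obj$treatment_effect$median_duration_single_complication),
    discount_rate_effects = obj$discounting$effects,
    discount_rate_costs = obj$discounting$costs,
    horizon = sim$horizon, cycle_length = sim$cycle_length,
    sex_mix = sim$sex_mix, life_table = life_table, wtp_grid = wtp,
    ert_start_rule = sim$ert_start_rule)
  p
}

# structural validation against the shipped schema
validate_params_schema <- function(obj) {
  schema <- jsonlite::fromJSON(
    system.file("extdata", "params_schema.json", package = "fabrycea",
                mustWork = TRUE))
  miss <- setdiff(schema$required, names(obj))
  if (length(miss)) {
    stop("parameter file is missing section(s): ",
         paste(miss, collapse = ", "))
  }
  check_fields <- function(tab, fields, what) {
    m <- setdiff(fields, names(tab))
    if (length(m)) {
      stop("parameter file section '", what, "' is missing field(s): ",
           paste(m, collapse = ", "))
    }
  }
  check_fields(obj$transitions, schema$transitions_fields, "transitions")
  check_fields(obj$death, schema$death_fields, "death")
  check_fields(obj$utilities, schema$utilities_keys, "utilities")
  check_fields(obj$costs, schema$costs_required, "costs")
  check_fields(obj$treatment_effect, schema$treatment_effect_required,
               "treatment_effect")
  check_fields(obj$discounting, schema$discounting_required, "discounting")
  check_fields(obj$simulation, schema$simulation_required, "simulation")
  bad <- setdiff(unlist(obj$states), state_names())
  if (length(bad)) stop("unknown state(s) in parameter file: ",
                        paste(bad, collapse = ", "))
  invisible(TRUE)
}

# derive beta shapes from 95% confidence limits where absent
add_beta_shapes <- function(tab) {
  if (is.null(tab$alpha)) tab$alpha <- NA_real_
  if (is.null(tab$beta)) tab$beta <- NA_real_
  if (!is.null(tab$lcl) && !is.null(tab$ucl)) {
    need <- is.na(tab$alpha) & !is.na(tab$lcl) & !is.na(tab$ucl) &
      tab$ucl > tab$lcl
    if (any(need)) {
      sd <- (tab$ucl[need] - tab$lcl[need]) / 3.92
      for (k in seq_along(which(need))) {
        i <- which(need)[k]
        sh <- beta_shapes_mom(tab$p[i], ((tab$ucl[i] - tab$lcl[i]) / 3.92)^2)
        tab$alpha[i] <- sh$alpha
        tab$beta[i] <- sh$beta
      }
    }
  }
  tab
}

#' Write a model parameter file
#'
#' @param params A `fabry_params` object.
#' @param path Output JSON path.
#' @param include_life_table Embed the life table in the JSON (default
#'   `FALSE`: the life table travels as its own delimited file).
#' @return `path`, invisibly.
#' @export
write_fabry_params <- function(params, path, include_life_table = FALSE) {
  obj <- list(
    states = state_names(),
    transitions = params$transitions,
    death = params$death,
    utilities = as.list(params$utilities),
    costs = list(state = as.list(params$cost_state),
                 production_loss = as.list(params$cost_production_loss),
                 ert_per_year = params$cost_ert,
                 unit_cost_hour = params$unit_cost_hour),
    treatment_effect = list(
      or_first = params$or_first, or_second = params$or_second,
      median_duration_symptoms = params$median_duration[["symptoms"]],
      median_duration_single_complication =
        params$median_duration[["single_complication"]]),
    discounting = list(effects = params$discount_rate_effects,
                       costs = params$discount_rate_costs),
    simulation = list(horizon = params$horizon,
                      cycle_length = params$cycle_length,
                      sex_mix = params$sex_mix,
                      ert_start_rule = params$ert_start_rule,
                      wtp_grid = params$wtp_grid))
  if (include_life_table) obj$life_table <- params$life_table
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
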