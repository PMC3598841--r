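#' Scenario identifiers
#'
#' @return Character vector of the base case and the six alternative
#'   scenario ids.
#' @export
scenario_ids <- function() {
  c("base", "s1_start40", "s2_utility_gap", "s3_classical_only",
    "s4_ace_arb", "s5_stop_after_2", "s6_production_loss")
}

#' Run the base case or one of the six alternative scenarios
#'
#' \describe{
#'   \item{base}{ERT from symptom onset versus standard care.}
#'   \item{s1_start40}{ERT start delayed until age 40.}
#'   \item{s2_utility_gap}{lower quality of life during the natural
#'     course: the comparator arm's cluster utilities are reduced by
#'     `utility_gap` (default 0.1), floored at 0.}
#'   \item{s3_classical_only}{classical-phenotype disease course: the
#'     analysis is run on the faster-progression parameter preset.}
#'   \item{s4_ace_arb}{standard care includes ACE inhibitors or
#'     angiotensin-receptor blockers, assumed as effective as ERT for
#'     risk reduction of a first complication: the comparator arm's
#'     symptoms-to-first-complication probabilities are multiplied by one
#'     minus the first-complication per-cycle relative risk reduction.
#'     The ERT arm is unchanged.}
#'   \item{s5_stop_after_2}{no ERT (no drug cost, no effect) once a
#'     second complication is present.}
#'   \item{s6_production_loss}{indirect non-medical costs of production
#'     loss added for cycles at age 18 and over, in both arms.}
#' }
#' Each scenario reduces to the base case when its override is neutral
#' (a zero utility gap, an identical preset, odds ratios of 1).
#'
#' @param id A scenario id from [scenario_ids()].
#' @param params The base parameter set.
#' @param params_classical Parameter set for `s3_classical_only`
#'   (default: the shipped classical preset).
#' @param utility_gap Utility decrement of the untreated arm in
#'   `s2_utility_gap` (default 0.1).
#' @return A `fabry_ce` object (discounted and undiscounted results).
#' @export
run_scenario <- function(id, params, params_classical = NULL,
                         utility_gap = 0.1) {
  if (!id %in% scenario_ids()) stop("unknown scenario id: ", id)
  switch(id,
    base = run_ce(params),
    s1_start40 = run_ce(params, strategy_treated = "ert_at_40"),
    s2_utility_gap = run_ce(params,
                            utility_offset_comparator = -utility_gap),
    s3_classical_only = {
      if (is.null(params_classical)) {
        params_classical <- generate_parameter_preset("classical")
      }
      run_ce(params_classical)
    },
    s4_ace_arb = {
      pc <- params
      rrr1 <- treatment_rrr_per_cycle(params)$first
      first <- pc$transitions$from == "symptoms" &
        pc$transitions$to %in% c("esrd", "cardiac", "cva")
      pc$transitions$p[first] <- pc$transitions$p[first] * (1 - rrr1)
      run_ce(params, params_comparator = pc)
    },
    s5_stop_after_2 = run_ce(params,
                             strategy_treated = "ert_stop_after_2"),
    s6_production_loss = run_ce(params, production_loss = TRUE))
}

#' Run the base case and all six scenarios
#'
#' @inheritParams run_scenario
#' @param ids Scenarios to run (default: all).
#' @return Named list of `fabry_ce` objects.
#' @export
run_all_scenarios <- function(params, ids = scenario_ids(),
                              params_classical = NULL) {
  stats::setNames(lapply(ids, run_scenario, params = params,
                         params_classical = params_classical), ids)
}

#' Univariate sensitivity analysis on the annual drug price
#'
#' Reruns the base-case comparison with the yearly ERT cost replaced.
#' Because the drug cost dominates the incremental costs, the ICERs move
#' nearly proportionally with the price.
#'
#' @param params The base parameter set.
#' @param new_price New annual ERT cost in euro (>= 0).
#' @return A `fabry_ce` object.
#' @export
sensitivity_drug_price <- function(params, new_price) {
  if (new_price < 0) stop("price must be >= 0")
  params$cost_ert <- new_price
  run_ce(params)
}

#' Scenario ICER table
#'
#' Collects discounted and undiscounted YFEOD- and QALY-based ICERs of a
#' set of scenario results into one table (one row per scenario).
#'
#' @param results Named list of `fabry_ce` objects, as returned by
#'   [run_all_scenarios()].
#' @return Data frame with columns `scenario`, `icer_yfeod_disc`,
#'   `icer_yfeod_undisc`, `icer_qaly_disc`, `icer_qaly_undisc`.
#' @export
scenario_icer_table <- function(results) {
  do.call(rbind, lapply(names(results), function(id) {
    ic <- results[[id]]$icers
    all_d <- ic[ic$sex == "all" & ic$discounting == "differential", ]
    all_u <- ic[ic$sex == "all" & ic$discounting == "none", ]
    data.frame(scenario = id,
               icer_yfeod_disc = all_d$icer_yfeod,
               icer_yfeod_undisc = all_u$icer_yfeod,
               icer_qaly_disc = all_d$icer_qaly,
               icer_qaly_undisc = all_u$icer_qaly,
               stringsAsFactors = FALSE)
  }))
}

#' Write the report tables of a full analysis
#'
#' Emits the effects table (YFEOD/QALYs per strategy, discounted and
#' undiscounted, by sex), the costs table, the ICER table, the scenario
#' ICER table and, if a PSA result is supplied, the CEAC data, as
#' delimited text files. A metadata file records the seed, package
#' version and a hash of the parameter set; partial inputs are marked
#' incomplete rather than silently omitted.
#'
#' @param results Named list of `fabry_ce` objects (must include
#'   `"base"`).
#' @param dir Output directory (created if needed).
#' @param params The parameter set used (hashed into the metadata).
#' @param psa Optional `fabry_psa` whose CEAC is exported.
#' @param seed Seed to record in the metadata.
#' @return Invisible character vector of the files written.
#' @export
report_tables <- function(results, dir, params = NULL, psa = NULL,
                          seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  complete <- "base" %in% names(results)
  base <- results[[if (complete) "base" else 1L]]
  eff <- merge(
    stats::setNames(base$arms$treated[c("sex", "yfeod", "qalys",
                                        "yfeod_disc", "qalys_disc")],
                    c("sex", "yfeod_ert", "qalys_ert", "yfeod_ert_disc",
                      "qalys_ert_disc")),
    stats::setNames(base$arms$comparator[c("sex", "yfeod", "qalys",
                                           "yfeod_disc", "qalys_disc")],
                    c("sex", "yfeod_no_ert", "qalys_no_ert",
                      "yfeod_no_ert_disc", "qalys_no_ert_disc")),
    by = "sex")
  f <- file.path(dir, "table_effects.csv")
  utils::write.csv(eff, f, row.names = FALSE)
  files <- c(files, f)
  cost <- merge(
    stats::setNames(base$arms$treated[c("sex", "cost", "cost_disc")],
                    c("sex", "cost_ert_arm", "cost_ert_arm_disc")),
    stats::setNames(base$arms$comparator[c("sex", "cost", "cost_disc")],
                    c("sex", "cost_no_ert_arm", "cost_no_ert_arm_disc")),
    by = "sex")
  cost$difference <- cost$cost_ert_arm - cost$cost_no_ert_arm
  cost$difference_disc <- cost$cost_ert_arm_disc - cost$cost_no_ert_arm_disc
  f <- file.path(dir, "table_costs.csv")
  utils::write.csv(cost, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "table_icers.csv")
  utils::write.csv(base$icers, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "table_scenarios.csv")
  utils::write.csv(scenario_icer_table(results), f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(psa)) {
    f <- file.path(dir, "ceac.csv")
    utils::write.csv(psa$ceac, f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(dir, "psa_draws.csv")
    utils::write.csv(psa$draws, f, row.names = FALSE)
    files <- c(files, f)
  }
  meta <- c(
    paste0("package_version: ",
           as.character(utils::packageVersion("fabrycea"))),
    paste0("seed: ", seed),
    paste0("scenarios: ", paste(names(results), collapse = ",")),
    paste0("status: ", if (complete) "complete" else "incomplete"),
    paste0("parameter_hash: ",
           if (is.null(params)) "none" else params_hash(params)))
  f <- file.path(dir, "run_metadata.txt")
  writeLines(meta, f)
  files <- c(files, f)
  invisible(files)
}

# md5 of the canonical JSON serialization of a parameter set
params_hash <- function(params) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_fabry_params(params, tf, include_life_table = TRUE)
  unname(tools::md5sum(tf))
}
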