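#' Incremental cost-effectiveness ratio
#'
#' Incremental cost divided by incremental effect, with the usual
#' cost-effectiveness-plane quadrant labels: `"dominant"` when the new
#' strategy is cheaper and more effective, `"dominated"` when it is more
#' expensive and less effective, and an undefined result (dominance check
#' required) when the effect difference is zero.
#'
#' @param delta_cost Incremental cost (euro).
#' @param delta_effect Incremental effect (YFEOD or QALYs).
#' @return List with `value` (euro per unit; `NA` when undefined) and
#'   `label`.
#' @export
icer <- function(delta_cost, delta_effect) {
  if (delta_effect == 0) {
    return(list(value = NA_real_,
                label = if (delta_cost == 0) "equivalent"
                        else "undefined, dominance check"))
  }
  label <- if (delta_cost <= 0 && delta_effect > 0) "dominant"
    else if (delta_cost > 0 && delta_effect < 0) "dominated"
    else "icer"
  list(value = delta_cost / delta_effect, label = label)
}

#' Net monetary benefit
#'
#' @param wtp Willingness to pay (euro per QALY, >= 0).
#' @param delta_qalys Incremental QALYs.
#' @param delta_cost Incremental cost (euro).
#' @return `wtp * delta_qalys - delta_cost` (euro).
#' @export
nmb <- function(wtp, delta_qalys, delta_cost) {
  if (any(wtp < 0)) stop("wtp must be >= 0")
  wtp * delta_qalys - delta_cost
}

#' QALYs per treatment-year needed for cost-effectiveness
#'
#' Given the incremental lifetime cost of treatment, a willingness-to-pay
#' per QALY and the length of the treatment window (years between symptom
#' onset and death), the number of QALYs that would have to be generated
#' in each treated year for the incremental cost to be worth paying:
#' `delta_cost / (wtp * window)`.
#'
#' @param delta_cost Incremental lifetime cost (euro).
#' @param wtp Willingness to pay (euro per QALY, > 0).
#' @param window Treatment window in years (> 0).
#' @return Required QALYs per treated year.
#' @export
required_qalys_per_year <- function(delta_cost, wtp, window) {
  if (wtp <= 0) stop("wtp must be > 0")
  if (window <= 0) stop("window must be > 0")
  delta_cost / (wtp * window)
}

#' Run one strategy arm of the cohort model
#'
#' Runs the deterministic cohort model for both sexes and combines them by
#' the cohort sex mix, returning undiscounted and discounted lifetime
#' outcomes.
#'
#' @param params A `fabry_params` object.
#' @param strategy An `ert_strategy` or its name.
#' @param production_loss Include productivity losses in costs.
#' @param utility_offset Additive shift applied to all living cluster
#'   utilities in this arm (floored at 0); used by the scenario that
#'   assumes a lower quality of life during the natural course.
#' @return A data frame with rows for `male`, `female` and `all` and
#'   columns for YFEOD, QALYs, life-years and cost components, discounted
#'   and undiscounted.
#' @export
run_arm <- function(params, strategy, production_loss = FALSE,
                    utility_offset = 0) {
  if (is.character(strategy)) strategy <- ert_strategy(strategy)
  util <- pmin(pmax(params$utilities + utility_offset, 0), 1)
  re <- params$discount_rate_effects
  rc <- params$discount_rate_costs
  one_sex <- function(sx) {
    tr <- run_cohort(params, strategy, sx)
    c0 <- accrue_costs(tr, params, 0, production_loss)
    cd <- accrue_costs(tr, params, rc, production_loss)
    data.frame(
      sex = sx,
      yfeod = accrue_yfeod(tr), qalys = accrue_qalys(tr, util),
      ly = accrue_life_years(tr),
      yfeod_disc = accrue_yfeod(tr, re),
      qalys_disc = accrue_qalys(tr, util, re),
      ly_disc = accrue_life_years(tr, re),
      cost = c0$total, cost_ert = c0$ert, cost_state = c0$state,
      cost_production = c0$production,
      cost_disc = cd$total, cost_ert_disc = cd$ert,
      cost_state_disc = cd$state, cost_production_disc = cd$production,
      stringsAsFactors = FALSE)
  }
  m <- one_sex("male"); f <- one_sex("female")
  w <- params$sex_mix
  all <- m
  all$sex <- "all"
  num <- vapply(m, is.numeric, logical(1))
  all[num] <- w * m[num] + (1 - w) * f[num]
  out <- rbind(m, f, all)
  rownames(out) <- NULL
  out
}

#' Compare ERT against a comparator strategy
#'
#' Runs the treated and comparator arms of the cohort model, computes the
#' incremental YFEOD, QALYs and costs per sex and overall, discounted and
#' undiscounted, and the incremental cost-effectiveness ratios.
#'
#' @param params A `fabry_params` object (used for the treated arm).
#' @param strategy_treated Strategy of the intervention arm (default: the
#'   parameter set's `ert_start_rule`).
#' @param strategy_comparator Strategy of the comparator arm (default
#'   `"no_ert"`, standard medical care).
#' @param params_comparator Parameter set for the comparator arm (defaults
#'   to `params`; a different set models e.g. ACE-ARB co-medication in the
#'   natural course).
#' @param utility_offset_comparator Additive utility shift in the
#'   comparator arm (e.g. -0.1 for a lower quality of life when
#'   untreated).
#' @param production_loss Include productivity losses in both arms.
#' @return An object of class `fabry_ce`: list with `arms` (per-arm
#'   outcome tables), `delta` and `icers` data frames (rows: sex x
#'   discounting).
#' @export
run_ce <- function(params, strategy_treated = NULL,
                   strategy_comparator = "no_ert",
                   params_comparator = NULL,
                   utility_offset_comparator = 0,
                   production_loss = FALSE) {
  if (is.null(strategy_treated)) {
    strategy_treated <- strategy_from_rule(params$ert_start_rule)
  }
  if (is.null(params_comparator)) params_comparator <- params
  a_t <- run_arm(params, strategy_treated, production_loss)
  a_c <- run_arm(params_comparator, strategy_comparator, production_loss,
                 utility_offset = utility_offset_comparator)
  delta <- do.call(rbind, lapply(seq_len(nrow(a_t)), function(i) {
    rbind(
      data.frame(sex = a_t$sex[i], discounting = "none",
                 d_yfeod = a_t$yfeod[i] - a_c$yfeod[i],
                 d_qalys = a_t$qalys[i] - a_c$qalys[i],
                 d_cost = a_t$cost[i] - a_c$cost[i]),
      data.frame(sex = a_t$sex[i], discounting = "differential",
                 d_yfeod = a_t$yfeod_disc[i] - a_c$yfeod_disc[i],
                 d_qalys = a_t$qalys_disc[i] - a_c$qalys_disc[i],
                 d_cost = a_t$cost_disc[i] - a_c$cost_disc[i]))
  }))
  icers <- delta
  icers$icer_yfeod <- vapply(seq_len(nrow(delta)), function(i)
    icer(delta$d_cost[i], delta$d_yfeod[i])$value, numeric(1))
  icers$icer_qaly <- vapply(seq_len(nrow(delta)), function(i)
    icer(delta$d_cost[i], delta$d_qalys[i])$value, numeric(1))
  structure(list(arms = list(treated = a_t, comparator = a_c),
                 delta = delta,
                 icers = icers[, c("sex", "discounting", "icer_yfeod",
                                   "icer_qaly")],
                 strategies = c(treated = if (is.character(strategy_treated))
                   strategy_treated else strategy_treated$name,
                   comparator = if (is.character(strategy_comparator))
                     strategy_comparator else strategy_comparator$name)),
            class = "fabry_ce")
}

#' @export
print.fabry_ce <- function(x, ...) {
  cat("Cost-effectiveness comparison:", x$strategies["treated"], "vs",
      x$strategies["comparator"], "\n\nIncremental outcomes:\n")
  d <- x$delta
  d$d_cost <- round(d$d_cost)
  d[c("d_yfeod", "d_qalys")] <- round(d[c("d_yfeod", "d_qalys")], 3)
  print(d, row.names = FALSE)
  cat("\nICERs (euro per unit):\n")
  ic <- x$icers
  ic[c("icer_yfeod", "icer_qaly")] <- round(ic[c("icer_yfeod", "icer_qaly")])
  print(ic, row.names = FALSE)
  invisible(x)
}

# draw one parameter realization from the stored beta shapes
draw_params <- function(params) {
  p2 <- params
  draw_tab <- function(tab) {
    if (is.null(tab$alpha)) return(tab)
    ok <- !is.na(tab$alpha) & !is.na(tab$beta)
    if (any(ok)) {
      tab$p[ok] <- stats::rbeta(sum(ok), tab$alpha[ok], tab$beta[ok])
    }
    tab
  }
  p2$transitions <- draw_tab(p2$transitions)
  p2$death <- draw_tab(p2$death)
  p2
}

#' Two-stage Monte Carlo probabilistic sensitivity analysis
#'
#' Outer (second-order) draws sample a full set of yearly transition
#' probabilities from their beta distributions; each draw runs a small
#' microsimulation (first-order trials) of the treated and comparator
#' strategies and records the incremental costs, QALYs and YFEOD. Net
#' monetary benefit is evaluated on the undiscounted deltas over the
#' willingness-to-pay grid, and summarised as a cost-effectiveness
#' acceptability curve. Utilities and costs are held fixed; only the
#' transition probabilities are varied.
#'
#' @param params A `fabry_params` with beta shapes (`alpha`, `beta`
#'   columns) on its transition and death tables.
#' @param n_outer Number of second-order draws (study design: 1000).
#' @param n_inner First-order trials per draw per arm (study design: 10).
#' @param wtp_grid Willingness-to-pay grid (defaults to the parameter
#'   set's grid).
#' @param seed Integer seed; the whole analysis is reproducible given it.
#' @param strategy_treated Intervention strategy (default: the parameter
#'   set's start rule).
#' @param common_random_numbers Reuse the same random stream for both arms
#'   within a draw (variance reduction; default `TRUE`).
#' @return An object of class `fabry_psa`: list with `draws` (per-draw
#'   deltas, undiscounted and discounted), `nmb` (draws x wtp matrix),
#'   `wtp`, `ceac` (data frame `wtp`, `probability`) and the settings.
#' @export
run_psa <- function(params, n_outer = 1000, n_inner = 10,
                    wtp_grid = params$wtp_grid, seed = 1,
                    strategy_treated = NULL,
                    common_random_numbers = TRUE) {
  if (is.null(strategy_treated)) {
    strategy_treated <- strategy_from_rule(params$ert_start_rule)
  }
  if (!any(!is.na(params$transitions$alpha))) {
    stop("no beta shape parameters on the transition table; ",
         "run the estimation stage or use a preset with uncertainty")
  }
  draws <- vector("list", n_outer)
  big <- 2147483647
  for (i in seq_len(n_outer)) {
    set.seed((seed + 7919 * i) %% big)
    p_i <- draw_params(params)
    arm_seed <- (seed + 7919 * i + 104729) %% big
    treat <- run_microsim(p_i, strategy_treated, n_inner, seed = arm_seed)
    comp_seed <- if (common_random_numbers) arm_seed else
      (arm_seed + 15485863) %% big
    comp <- run_microsim(p_i, "no_ert", n_inner, seed = comp_seed)
    d <- treat$mean - comp$mean
    draws[[i]] <- data.frame(
      draw = i,
      d_cost = d[["cost"]], d_qalys = d[["qalys"]], d_yfeod = d[["yfeod"]],
      d_cost_disc = d[["cost_disc"]], d_qalys_disc = d[["qalys_disc"]],
      d_yfeod_disc = d[["yfeod_disc"]])
  }
  draws <- do.call(rbind, draws)
  nmb_m <- outer(draws$d_qalys, wtp_grid) - draws$d_cost
  colnames(nmb_m) <- signif(wtp_grid, 6)
  psa <- structure(list(draws = draws, nmb = nmb_m, wtp = wtp_grid,
                        settings = list(n_outer = n_outer,
                                        n_inner = n_inner, seed = seed,
                                        common_random_numbers =
                                          common_random_numbers)),
                   class = "fabry_psa")
  psa$ceac <- ceac(psa)
  psa
}

#' Cost-effectiveness acceptability curve
#'
#' The probability of the intervention being cost-effective at each
#' willingness-to-pay value: the fraction of outer draws with a positive
#' net monetary benefit.
#'
#' @param psa A `fabry_psa` object.
#' @return Data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa) {
  data.frame(wtp = psa$wtp,
             probability = colMeans(psa$nmb > 0))
}

#' @export
print.fabry_psa <- function(x, ...) {
  s <- x$settings
  cat("Probabilistic sensitivity analysis:", s$n_outer, "outer draws x",
      s$n_inner, "first-order trials (seed", paste0(s$seed, ")"), "\n")
  cat("  mean incremental cost :",
      format(round(mean(x$draws$d_cost)), big.mark = ","), "euro\n")
  cat("  mean incremental QALYs:", round(mean(x$draws$d_qalys), 3), "\n")
  cat("  CEAC range:", round(min(x$ceac$probability), 3), "-",
      round(max(x$ceac$probability), 3), "\n")
  invisible(x)
}
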