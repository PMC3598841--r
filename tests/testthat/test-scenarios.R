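p_base <- generate_parameter_preset("base")
ce_base <- run_scenario("base", p_base)

icer_of <- function(ce, which = "icer_qaly", disc = "none") {
  ic <- ce$icers
  ic[ic$sex == "all" & ic$discounting == disc, which]
}

test_that("neutral overrides reproduce the base case exactly", {
  s2_zero <- run_scenario("s2_utility_gap", p_base, utility_gap = 0)
  expect_equal(s2_zero$delta, ce_base$delta, tolerance = 1e-12)
  s3_same <- run_scenario("s3_classical_only", p_base,
                          params_classical = p_base)
  expect_equal(s3_same$icers, ce_base$icers, tolerance = 1e-12)
  # with a null treatment effect, the ACE-ARB override is a no-op
  p0 <- generate_parameter_preset("null-effect")
  expect_equal(run_scenario("s4_ace_arb", p0)$delta,
               run_scenario("base", p0)$delta, tolerance = 1e-12)
  expect_error(run_scenario("s9_unknown", p_base), "unknown scenario")
})

test_that("a 0.1 utility gap in the natural course slashes the QALY ICER", {
  s2 <- run_scenario("s2_utility_gap", p_base)
  # the published pattern: the undiscounted QALY ICER drops by ~80%
  drop <- 1 - icer_of(s2) / icer_of(ce_base)
  expect_gt(drop, 0.7)
  expect_lt(drop, 0.9)
  # YFEOD is untouched by a utility offset
  expect_equal(icer_of(s2, "icer_yfeod"), icer_of(ce_base, "icer_yfeod"))
})

test_that("delaying ERT to age 40 inflates the undiscounted ICERs", {
  s1 <- run_scenario("s1_start40", p_base)
  expect_gt(icer_of(s1, "icer_yfeod"), icer_of(ce_base, "icer_yfeod"))
  # discounting helps this scenario far more than the base case
  cut_s1 <- 1 - icer_of(s1, "icer_yfeod", "differential") /
    icer_of(s1, "icer_yfeod", "none")
  cut_base <- 1 - icer_of(ce_base, "icer_yfeod", "differential") /
    icer_of(ce_base, "icer_yfeod", "none")
  expect_gt(cut_s1, cut_base)
})

test_that("classical-phenotype progression yields somewhat lower ICERs", {
  s3 <- run_scenario("s3_classical_only", p_base)
  expect_lt(icer_of(s3), icer_of(ce_base))
  expect_lt(icer_of(s3, "icer_yfeod"), icer_of(ce_base, "icer_yfeod"))
})

test_that("ACE-ARB in the natural course erodes the value of ERT", {
  s4 <- run_scenario("s4_ace_arb", p_base)
  expect_gt(icer_of(s4), icer_of(ce_base))
  expect_gt(icer_of(s4, "icer_yfeod"), icer_of(ce_base, "icer_yfeod"))
})

test_that("stopping ERT after two complications changes little", {
  s5 <- run_scenario("s5_stop_after_2", p_base)
  expect_lt(abs(icer_of(s5) / icer_of(ce_base) - 1), 0.05)
  # drug cost strictly lower without double/triple-state treatment
  expect_lt(s5$arms$treated$cost_ert[3], ce_base$arms$treated$cost_ert[3])
})

test_that("production-loss costs marginally affect the ICERs", {
  s6 <- run_scenario("s6_production_loss", p_base)
  expect_lt(abs(icer_of(s6) / icer_of(ce_base) - 1), 0.01)
  expect_gt(s6$arms$treated$cost_production[3], 0)
  expect_equal(ce_base$arms$treated$cost_production[3], 0)
})

test_that("discounting improves all scenario ICERs", {
  res <- run_all_scenarios(p_base)
  tab <- scenario_icer_table(res)
  expect_equal(nrow(tab), 7)
  expect_true(all(tab$icer_yfeod_disc < tab$icer_yfeod_undisc))
  expect_true(all(tab$icer_qaly_disc < tab$icer_qaly_undisc))
})

test_that("ICERs are more favourable for males than for females", {
  ic <- ce_base$icers
  for (d in c("none", "differential")) {
    expect_lt(ic$icer_qaly[ic$sex == "male" & ic$discounting == d],
              ic$icer_qaly[ic$sex == "female" & ic$discounting == d])
    expect_lt(ic$icer_yfeod[ic$sex == "male" & ic$discounting == d],
              ic$icer_yfeod[ic$sex == "female" & ic$discounting == d])
  }
})

test_that("drug-price sensitivity scales the ICER nearly proportionally", {
  same <- sensitivity_drug_price(p_base, 200000)
  expect_equal(same$icers, ce_base$icers, tolerance = 1e-12)
  cheap <- sensitivity_drug_price(p_base, 150000)
  cut <- 1 - icer_of(cheap) / icer_of(ce_base)
  expect_gt(cut, 0.20)
  expect_lt(cut, 0.26)
  free <- sensitivity_drug_price(p_base, 0)
  d_free <- free$delta[free$delta$sex == "all" &
                         free$delta$discounting == "none", "d_cost"]
  non_drug <- free$arms$treated$cost_state[3] -
    free$arms$comparator$cost_state[3]
  expect_equal(d_free, non_drug, tolerance = 1e-9)
  expect_error(sensitivity_drug_price(p_base, -1), "price")
})

test_that("report tables are written completely and reproducibly", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  res <- run_all_scenarios(p_base, ids = c("base", "s1_start40"))
  f1 <- report_tables(res, dir1, params = p_base, seed = 1)
  f2 <- report_tables(res, dir2, params = p_base, seed = 1)
  expect_true(all(file.exists(f1)))
  expect_setequal(basename(f1),
                  c("table_effects.csv", "table_costs.csv",
                    "table_icers.csv", "table_scenarios.csv",
                    "run_metadata.txt"))
  tab6 <- read.csv(file.path(dir1, "table_scenarios.csv"))
  expect_equal(nrow(tab6), 2)
  for (f in setdiff(basename(f1), "run_metadata.txt")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  meta <- readLines(file.path(dir1, "run_metadata.txt"))
  expect_true(any(grepl("parameter_hash", meta)))
  expect_true(any(grepl("status: complete", meta)))
})
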