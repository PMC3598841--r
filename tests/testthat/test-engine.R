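test_that("an immortal asymptomatic cohort accrues 70 of everything", {
  par <- toy_params()  # no exits, no deaths, utilities 1
  tr <- run_cohort(par, "no_ert", "male")
  expect_equal(accrue_yfeod(tr), 70)
  expect_equal(accrue_life_years(tr), 70)
  expect_equal(accrue_qalys(tr, par$utilities), 70)
  expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-10))
})

test_that("a constant death hazard reproduces the geometric series", {
  par <- toy_params(p_death = 0.1)
  tr <- run_cohort(par, "no_ert", "female")
  # sum_{t=1..70} 0.9^t, closed form
  expected <- 0.9 * (1 - 0.9^70) / (1 - 0.9)
  expect_equal(accrue_life_years(tr), expected, tolerance = 1e-9)
})

test_that("discount factors follow 1/(1+r)^t with an undiscounted first cycle", {
  expect_equal(discount_factor(0, 0:10), rep(1, 11))
  expect_equal(discount_factor(0.04, 1), 1 / 1.04)
  expect_equal(discount_factor(0.04, 0), 1)
  f <- discount_factor(0.015, 0:69)
  expect_true(all(diff(f) < 0))
  expect_error(discount_factor(-0.01, 1), "rate")
})

test_that("YFEOD counts only the damage-free states, linearly", {
  tr_cardiac <- manual_trace("cardiac", 10)
  expect_equal(accrue_yfeod(tr_cardiac), 0)
  half <- setNames(rep(0, 11), state_names())
  half[c("symptoms", "cva")] <- 0.5
  expect_equal(accrue_yfeod(manual_trace(half, 10)), 5)
})

test_that("QALY accrual weights occupancy by cluster utility", {
  u <- c(asymptomatic = 0.874, acro_or_symptoms = 0.762,
         single_complication = 0.744, multiple_complications = 0.584)
  tr <- manual_trace("asymptomatic", 70)
  expect_equal(accrue_qalys(tr, u), 70 * 0.874)
  expect_equal(accrue_qalys(tr, u, rate = 0.015),
               0.874 * sum(1 / 1.015^(0:69)))
  ones <- setNames(rep(1, 4), names(u))
  expect_equal(accrue_qalys(tr, ones), accrue_life_years(tr))
  expect_equal(accrue_qalys(tr, 0 * ones), 0)
  expect_error(accrue_qalys(tr, u[1:2]), "missing utility")
})

test_that("cost accrual separates state, drug and production components", {
  par <- toy_params()
  tr <- manual_trace("symptoms", 70, treated = TRUE)
  out <- accrue_costs(tr, par)
  expect_equal(out$ert, 70 * 200000)  # 14 million over 70 years
  expect_equal(out$state, 0)
  tr_untreated <- manual_trace("symptoms", 70, treated = FALSE)
  expect_equal(accrue_costs(tr_untreated, par)$ert, 0)
  # 100/yr state cost at 4%: geometric series over 70 cycles
  par2 <- toy_params(cost_state = setNames(rep(100, 10),
                                           setdiff(state_names(), "death")))
  disc <- accrue_costs(tr_untreated, par2, rate = 0.04)
  expect_equal(disc$state, 100 * sum(1 / 1.04^(0:69)), tolerance = 1e-9)
  expect_equal(disc$state, 2433.0296, tolerance = 1e-4)
  # production loss only from age 18 onward
  par3 <- toy_params()
  par3$cost_production_loss <- c(asymptomatic = 0, acro_or_symptoms = 1000,
                                 single_complication = 0,
                                 multiple_complications = 0)
  pl <- accrue_costs(tr_untreated, par3, production_loss = TRUE)
  expect_equal(pl$production, 1000 * sum(0:69 + 1 >= 18))
})

test_that("null treatment effect leaves traces identical except drug cost", {
  p0 <- generate_parameter_preset("null-effect")
  tr_ert <- run_cohort(p0, "ert_at_symptoms", "male")
  tr_no <- run_cohort(p0, "no_ert", "male")
  expect_equal(tr_ert$occupancy, tr_no$occupancy, tolerance = 1e-14)
  expect_equal(accrue_qalys(tr_ert, p0$utilities),
               accrue_qalys(tr_no, p0$utilities))
  expect_gt(accrue_costs(tr_ert, p0)$ert, 0)
  expect_equal(accrue_costs(tr_no, p0)$ert, 0)
})

test_that("strategies treat the documented states and ages", {
  s <- ert_strategy("ert_at_symptoms")$treated(10)
  expect_false(s[["asymptomatic"]] || s[["acroparesthesia"]] ||
                 s[["death"]])
  expect_true(s[["symptoms"]] && s[["esrd"]] && s[["esrd_cardiac_cva"]])
  s40 <- ert_strategy("ert_at_40")
  expect_false(any(s40$treated(39)))
  expect_true(s40$treated(40)[["symptoms"]])
  s2 <- ert_strategy("ert_stop_after_2")$treated(50)
  expect_true(s2[["symptoms"]] && s2[["cardiac"]])
  expect_false(s2[["esrd_cardiac"]] || s2[["esrd_cardiac_cva"]])
  expect_false(any(ert_strategy("no_ert")$treated(50)))
})

test_that("cohort invariants hold on the base preset", {
  p <- generate_parameter_preset("base")
  for (strat in c("no_ert", "ert_at_symptoms", "ert_at_40")) {
    tr <- run_cohort(p, strat, "male")
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-10))
    expect_true(all(tr$occupancy >= -1e-15))
    expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-15))
    ly <- accrue_life_years(tr)
    yf <- accrue_yfeod(tr)
    expect_lte(yf, ly + 1e-9)
    expect_lte(ly, 70)
    expect_lte(accrue_yfeod(tr, 0.015), yf)
    expect_lte(accrue_qalys(tr, p$utilities, 0.015),
               accrue_qalys(tr, p$utilities))
  }
})

test_that("treatment never reduces years free of end-organ damage", {
  p <- generate_parameter_preset("base")
  for (sx in c("male", "female")) {
    yf_t <- accrue_yfeod(run_cohort(p, "ert_at_symptoms", sx))
    yf_u <- accrue_yfeod(run_cohort(p, "no_ert", sx))
    expect_gte(yf_t, yf_u)
  }
})

test_that("microsimulation is seed-reproducible and sex-consistent", {
  p <- generate_parameter_preset("base")
  a <- run_microsim(p, "ert_at_symptoms", 10, seed = 5)
  b <- run_microsim(p, "ert_at_symptoms", 10, seed = 5)
  expect_identical(a, b)
  one <- run_microsim(p, "no_ert", 1, seed = 9)
  expect_identical(one$outcomes,
                   run_microsim(p, "no_ert", 1, seed = 9)$outcomes)
  # immortal toy: every trajectory survives all 70 cycles
  par <- toy_params()
  ms <- run_microsim(par, "no_ert", 25, seed = 2)
  expect_true(all(ms$outcomes$ly == 70))
})

test_that("microsimulation means approach the cohort expectation", {
  p <- generate_parameter_preset("base")
  ce <- run_arm(p, "no_ert")
  ms <- run_microsim(p, "no_ert", 4000, seed = 123)
  for (col in c("yfeod", "qalys", "ly")) {
    se <- sd(ms$outcomes[[col]]) / sqrt(nrow(ms$outcomes))
    expect_lt(abs(mean(ms$outcomes[[col]]) - ce[[col]][ce$sex == "all"]),
              3 * se)
  }
})

test_that("trace export has one row per cycle with occupancies", {
  p <- generate_parameter_preset("base")
  d <- as.data.frame(run_cohort(p, "no_ert", "male"))
  expect_equal(nrow(d), 70)
  expect_true(all(state_names() %in% names(d)))
  expect_equal(d$alive, 1 - d$death)
})
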