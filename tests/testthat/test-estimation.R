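test_that("km_median matches a hand-computed product-limit table", {
  # all events at t = 2: survival drops to 0 there
  expect_equal(km_median(rep(2, 5), rep(1, 5))$median, 2)
  # times 1..5, the t=3 subject censored: S = 0.8, 0.6, then at t=4
  # 0.6 * (1 - 1/2) = 0.3 <= 0.5, so the median is 4
  km <- km_median(1:5, c(1, 1, 0, 1, 1))
  expect_equal(km$median, 4)
  expect_true(km$reached)
  # brute-force product-limit agreement on small fixtures
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    times <- round(rexp(n, 0.5) + 0.1, 3)
    events <- rbinom(n, 1, 0.8)
    if (!any(events == 1)) next
    ot <- sort(unique(times[events == 1]))
    surv <- 1
    med <- NA
    for (tt in ot) {
      at_risk <- sum(times >= tt)
      d <- sum(times == tt & events == 1)
      surv <- surv * (1 - d / at_risk)
      if (is.na(med) && surv <= 0.5 + 1e-12) med <- tt
    }
    if (!is.na(med)) {
      expect_equal(km_median(times, events)$median, med)
    } else {
      km <- km_median(times, events)
      expect_false(km$reached)
      expect_equal(km$median, max(times[events == 1]))
    }
  }
})

test_that("km_median is consistent for exponential data and errors without events", {
  set.seed(1)
  x <- rexp(5000, log(2))  # true median 1
  expect_lt(abs(km_median(x, rep(1, 5000))$median - 1), 0.05)
  expect_error(km_median(c(1, 2), c(0, 0)), "median undefined")
  expect_error(km_median(c(0, 2), c(1, 1)), "times must be > 0")
})

test_that("median-to-probability conversion is the constant-hazard formula", {
  expect_equal(annual_probability_from_median(1), 0.5)
  expect_equal(annual_probability_from_median(2), 1 - 2^(-1 / 2))
  # strictly decreasing in the median, approaching 0
  meds <- c(0.5, 1, 2, 5, 20, 100, 1e6)
  ps <- annual_probability_from_median(meds)
  expect_true(all(diff(ps) < 0))
  expect_lt(ps[length(ps)], 1e-6)
  expect_error(annual_probability_from_median(0), "median must be > 0")
  # round-trips with its inverse
  expect_equal(fabrycea:::median_from_annual_probability(
    annual_probability_from_median(3.7)), 3.7)
})

test_that("EQ-5D utilities evaluate the tariff with the full-health anchor", {
  uk <- read_tariff("uk_tto")
  nl <- read_tariff("nl_tto")
  expect_equal(eq5d_utility(c(1, 1, 1, 1, 1), uk), 1.0)
  expect_equal(eq5d_utility(c(1, 1, 1, 1, 1), nl), 1.0)
  # one dimension at level 2: 1 - constant - that dimension's decrement
  expect_equal(eq5d_utility(c(1, 1, 1, 1, 2), uk), 1 - 0.081 - 0.071)
  expect_error(eq5d_utility(c(1, 1, 1, 4, 1), uk), "levels")
  expect_error(eq5d_utility(c(1, 1, 1, 1), uk), "5 dimensions")
})

test_that("Dutch tariff values exceed UK values on the fixture profiles", {
  uk <- read_tariff("uk_tto")
  nl <- read_tariff("nl_tto")
  fixtures <- list(c(2, 1, 1, 2, 1), c(2, 2, 2, 2, 2), c(1, 1, 2, 2, 1),
                   c(1, 2, 2, 2, 3), c(3, 3, 3, 3, 3))
  for (pr in fixtures) {
    expect_gte(eq5d_utility(pr, nl), eq5d_utility(pr, uk))
  }
})

test_that("cluster utilities use two-stage (per-patient first) averaging", {
  uk <- read_tariff("uk_tto")
  # patient A has two questionnaires, patient B one, same cluster
  rec <- data.frame(patient_id = c("A", "A", "B"), quarter = c(1, 2, 1),
                    state = "asymptomatic",
                    MO = c(1, 1, 2), SC = 1, UA = c(2, 1, 2), PD = 1,
                    AD = c(1, 1, 2))
  u <- vapply(seq_len(3), function(i)
    eq5d_utility(as.integer(rec[i, 4:8]), uk), numeric(1))
  two_stage <- mean(c(mean(u[1:2]), u[3]))
  pooled <- mean(u)
  res <- mean_utility_by_cluster(rec, uk, n_boot = 100, seed = 1)
  expect_equal(res$mean, two_stage)
  expect_false(isTRUE(all.equal(two_stage, pooled)))
  # with one record per patient the two coincide
  rec1 <- rec[c(1, 3), ]
  res1 <- mean_utility_by_cluster(rec1, uk, n_boot = 100, seed = 1)
  expect_equal(res1$mean, mean(u[c(1, 3)]))
})

test_that("synthetic EQ-5D data reproduce the cohort's asymptomatic utility", {
  cfg <- synth_config("base", n_patients = 400, seed = 21)
  rec <- generate_eq5d(cfg)
  res <- mean_utility_by_cluster(rec, read_tariff("uk_tto"),
                                 n_boot = 200, seed = 2)
  asym <- res[res$cluster == "asymptomatic", ]
  # published asymptomatic cluster mean 0.874, 95% CI 0.804-0.934
  expect_gt(asym$mean, 0.804)
  expect_lt(asym$mean, 0.934)
})

test_that("annual costs are quarterly costs x4 averaged per patient then cluster", {
  rec <- data.frame(patient_id = 1, quarter = 1, state = "symptoms",
                    gp_visit = 2)
  out <- mean_annual_cost_by_cluster(rec, c(gp_visit = 28))
  expect_equal(out$mean_annual_cost, 2 * 28 * 4)
  rec$gp_visit <- 0
  expect_equal(mean_annual_cost_by_cluster(rec,
    c(gp_visit = 28))$mean_annual_cost, 0)
  expect_error(mean_annual_cost_by_cluster(
    data.frame(patient_id = 1, quarter = 1, state = "symptoms", mri = 1),
    c(gp_visit = 28)), "mri")
})

test_that("production loss follows the sick-leave costing rules", {
  base <- data.frame(patient_id = 1:3, quarter = 1, state = "symptoms",
                     sick_days_fortnight = c(1, 0, 0),
                     hours_per_day = 8, days_per_week = 5,
                     employment = c("employed", "permanent_sick_leave",
                                    "not_employed_other"))
  out <- annual_production_loss(base[1, ])
  expect_equal(out$mean_annual_loss, 1 * 26 * 8 * 30)  # 6240
  out2 <- annual_production_loss(base[2, ])
  expect_equal(out2$mean_annual_loss, 52 * 5 * 8 * 30)  # 62400
  # the permanent-sick-leave FTE uses the employed mean hours; with no
  # employed patient in the record set it falls back to the row's own hours
  out3 <- annual_production_loss(base)
  expect_equal(out3$mean_annual_loss, mean(c(6240, 62400, 0)))
  bad <- base[1, ]; bad$sick_days_fortnight <- -1
  expect_error(annual_production_loss(bad), "sick leave")
})

test_that("bootstrap beta summaries recover means and respect bounds", {
  const <- bootstrap_beta_ci(rep(0.5, 20), n_boot = 200, seed = 1)
  expect_true(const$degenerate)
  expect_equal(c(const$mean, const$lcl, const$ucl), rep(0.5, 3))
  set.seed(7)
  x <- rbeta(500, 2, 8)
  b <- bootstrap_beta_ci(x, n_boot = 500, seed = 2)
  expect_lt(abs(b$mean - 0.2), 0.03)
  expect_true(b$lcl <= b$mean && b$mean <= b$ucl)
  expect_true(b$lcl >= 0 && b$ucl <= 1)
  expect_true(b$alpha > 0 && b$beta > 0)
  # reproducible under a fixed seed
  b2 <- bootstrap_beta_ci(x, n_boot = 500, seed = 2)
  expect_identical(b, b2)
  expect_error(bootstrap_beta_ci(c(0.2, 1.2)), "\\[0,1\\]")
})

test_that("transition estimation recovers generating probabilities", {
  cfg <- synth_config("base", n_patients = 1200, seed = 31)
  h <- generate_histories(cfg)
  est <- estimate_transition_probabilities(h)
  truth <- generate_parameter_preset("base")$transitions
  m <- merge(est, truth, by = c("from", "to", "sex"),
             suffixes = c("_est", "_true"))
  # the well-populated early-disease edges are recovered closely
  early <- m[m$from %in% c("asymptomatic", "acroparesthesia"), ]
  expect_gte(nrow(early), 5)
  expect_true(all(abs(early$p_est / early$p_true - 1) < 0.2))
  # pooled mode reports the same estimate for both sexes
  pooled <- estimate_transition_probabilities(h, by_sex = FALSE)
  expect_equal(attr(pooled, "mode"), "pooled")
  one <- pooled[pooled$from == "asymptomatic" &
                  pooled$to == "acroparesthesia", ]
  expect_equal(length(unique(one$p)), 1L)
})
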