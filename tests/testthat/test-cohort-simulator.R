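test_that("event-year draws follow the hazard schedule", {
  set.seed(11)
  expect_true(all(is.na(draw_event_year(rep(0, 20), 100))))
  first <- draw_event_year(c(1, rep(0.5, 19)), 100)
  expect_true(all(first > 0 & first <= 12))
  # constant hazard calibrated to 67.9% twenty-year survival: the absent
  # fraction matches the closed form at Monte-Carlo precision
  h <- 1 - 0.679^(1 / 20)
  t <- draw_event_year(rep(h, 20), 1e5)
  expect_within_binomial_ci(mean(is.na(t)), 0.679, 1e5)
  expect_true(all(t[!is.na(t)] > 0 & t[!is.na(t)] <= 240))
  expect_error(draw_event_year(c(0.5, 1.2)), "probabilities")
})

test_that("endpoint classification enumerates the event orderings", {
  # no events; other death only
  expect_equal(classify_endpoint(NA, NA), "E1")
  expect_equal(classify_endpoint(NA, 100), "E2")
  # destined tumor death at 120 months, metastasis at 92:
  expect_equal(classify_endpoint(120, NA), "E4")   # no competing event
  expect_equal(classify_endpoint(120, 130), "E4")  # tumor death first
  expect_equal(classify_endpoint(120, 80), "E5")   # other death before MET
  expect_equal(classify_endpoint(120, 100), "E6")  # other death after MET
  expect_equal(classify_endpoint(120, 92), "E6")   # boundary: at MET
  expect_equal(classify_endpoint(120, 120), "E6")  # tie -> tumor-independent
  # vectorized
  expect_equal(classify_endpoint(c(NA, 120, 120), c(50, 80, NA)),
               c("E2", "E5", "E4"))
  expect_error(classify_endpoint(-3, 10), "positive")
})

test_that("no competing mortality: tumor survival is recovered and corrections vanish", {
  d <- small_demography()
  lt0 <- zero_mortality_life_table()
  for (arm in c("ms", "no_ms")) {
    cal <- arm_calibration(arm)
    spec <- cohort_spec(50, arm, n_women = 5e4, replicates = 2, seed = 3)
    tal <- simulate_cohort_replicates(spec, build_schedule(cal),
                                      life_table = lt0,
                                      incidence = d$incidence)
    expect_equal(tal$e2, 0)
    expect_equal(tal$e5, 0)
    expect_equal(tal$e6, 0)
    expect_equal(tal$e3, tal$e4)
    expect_equal(tal$ll, tal$ll_corr)
    n_eff <- tal$n_bc * spec$replicates
    expect_within_binomial_ci(1 - tal$e3, cal$s20, n_eff)
  }
})

test_that("no tumor mortality: E3 and the loss tallies are zero", {
  d <- small_demography()
  spec <- cohort_spec(60, "ms", n_women = 2e4, replicates = 1, seed = 5)
  off <- build_schedule(arm_calibration("ms"), no_tumor_mortality = TRUE)
  tal <- simulate_cohort_replicates(spec, off, d)
  expect_equal(tal$e3, 0)
  expect_equal(tal$ll, 0)
  expect_equal(tal$yll, 0)
  expect_equal(tal$e1 + tal$e2, 1)
})

test_that("conservation holds in every replicate across ages, arms and accrual modes", {
  d <- small_demography()
  for (mode in c("across-rounds", "at-entry")) {
    for (a in c(40, 64, 80)) {
      for (arm in c("ms", "no_ms")) {
        spec <- cohort_spec(a, arm, cohort_n_women(d$population, a),
                            accrual_mode = mode, replicates = 4, seed = 17)
        tal <- simulate_cohort_replicates(spec, build_schedule(arm_calibration(arm)), d)
        reps <- attr(tal, "replicates")
        expect_equal(reps$e1 + reps$e2 + reps$e3, rep(1, nrow(reps)),
                     tolerance = 1e-9)
        expect_equal(reps$e3, reps$e4 + reps$e5 + reps$e6, tolerance = 1e-9)
        # correction identities per replicate: counts, so exact
        expect_equal(reps$ll_corr / reps$ll, reps$e4 / reps$e3, tolerance = 1e-9)
        expect_true(all(reps$ll_corr <= reps$ll))
        expect_true(all(reps$yll_corr <= reps$yll))
      }
    }
  }
})

test_that("expected number of diagnoses follows incidence x woman-years", {
  d <- small_demography()
  n_women <- 5e4
  spec <- cohort_spec(50, "ms", n_women, replicates = 20, seed = 23)
  tal <- simulate_cohort_replicates(spec, build_schedule(arm_calibration("ms")), d)
  inc <- d$incidence
  expected <- sum(n_women * inc$rate_per_100k[inc$age %in% 50:69] / 1e5)
  expect_equal(tal$n_bc, expected, tolerance = 0.02)
})

test_that("replicate aggregation averages and reports dispersion", {
  d <- small_demography()
  spec <- cohort_spec(60, "no_ms", 2e4, replicates = 1, seed = 31)
  set.seed(1)
  one <- simulate_cohort(spec, build_schedule(arm_calibration("no_ms")),
                         d$life_table, d$incidence)
  agg <- aggregate_replicates(list(one, one, one))
  expect_equal(agg$e3, one$e3)
  expect_equal(agg$ll, one$ll)
  expect_equal(agg$se_e3, 0)
  expect_equal(agg$e1 + agg$e2 + agg$e3, 1, tolerance = 1e-9)
  expect_error(aggregate_replicates(list()), "no replicates")
  # replicate averaging shrinks the standard error roughly as 1/sqrt(R)
  spec50 <- cohort_spec(60, "no_ms", 2e4, replicates = 50, seed = 31)
  agg50 <- simulate_cohort_replicates(spec50, build_schedule(arm_calibration("no_ms")), d)
  reps <- attr(agg50, "replicates")
  sd_single <- stats::sd(reps$e3)
  expect_equal(agg50$se_e3, sd_single / sqrt(50))
  expect_lt(agg50$se_e3, sd_single / 5)
})

test_that("simulation is reproducible from the master seed and arms are independent", {
  d <- small_demography()
  spec <- cohort_spec(56, "ms", 2e4, replicates = 3, seed = 41)
  sch <- build_schedule(arm_calibration("ms"))
  a <- simulate_cohort_replicates(spec, sch, d)
  b <- simulate_cohort_replicates(spec, sch, d)
  expect_equal(as.data.frame(a), as.data.frame(b))
  spec2 <- cohort_spec(56, "ms", 2e4, replicates = 3, seed = 42)
  c2 <- simulate_cohort_replicates(spec2, sch, d)
  expect_false(isTRUE(all.equal(a$ll, c2$ll)))
})

test_that("demography gaps raise validation errors", {
  d <- small_demography()
  trunc_inc <- d$incidence[d$incidence$age <= 60, ]
  spec <- cohort_spec(50, "ms", 1e4, replicates = 1, seed = 1)
  expect_error(simulate_cohort(spec, build_schedule(arm_calibration("ms")),
                               d$life_table, trunc_inc),
               "incidence table must cover")
  late_lt <- d$life_table[d$life_table$age >= 60, ]
  expect_error(simulate_cohort(spec, build_schedule(arm_calibration("ms")),
                               late_lt, d$incidence),
               "life table starts")
})
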