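make_tally <- function(entry_age, arm, n_women, ll, ll_corr, yll, yll_corr,
                       n_bc = 1000) {
  structure(data.frame(entry_age = entry_age, arm = arm, n_women = n_women,
                       n_bc = n_bc, e1 = NA, e2 = NA,
                       e3 = ll / n_bc, e4 = ll_corr / n_bc, e5 = NA, e6 = NA,
                       ll = ll, ll_corr = ll_corr, yll = yll,
                       yll_corr = yll_corr, stringsAsFactors = FALSE),
            class = c("endpoint_tally", "data.frame"))
}

test_that("arm comparison computes the benefit and cost identities", {
  ms <- make_tally(48, "ms", 54000, ll = 411, ll_corr = 397,
                   yll = 10740, yll_corr = 10309)
  noms <- make_tally(48, "no_ms", 54000, ll = 733, ll_corr = 708,
                     yll = 19524, yll_corr = 18780)
  s <- compare_arms(ms, noms)
  expect_equal(s$pd, 322)
  expect_equal(s$pd_corr, 311)
  expect_equal(s$mse, 540000)
  expect_equal(s$mse_per_pd_corr, 540000 / 311)
  expect_equal(s$cost_per_pd_corr, 88 * s$mse_per_pd_corr)
  expect_equal(s$ly_corr, 18780 - 10309)
  expect_equal(s$cost_per_ly_corr, 88 * s$mse_per_ly_corr)
  expect_equal(s$pd_per_10k * s$mse_per_pd_corr, 1e4)
  expect_equal(s$ly_per_10k * s$mse_per_ly_corr, 1e4)
})

test_that("identical tallies give zero benefit and not-estimable ratios", {
  ms <- make_tally(60, "ms", 1e4, 500, 450, 9000, 8500)
  noms <- make_tally(60, "no_ms", 1e4, 500, 450, 9000, 8500)
  s <- compare_arms(ms, noms)
  expect_equal(s$pd, 0)
  expect_equal(s$pd_corr, 0)
  expect_true(is.na(s$mse_per_pd_corr))
  expect_true(is.na(s$cost_per_pd_corr))
  expect_true(is.na(s$pd_per_10k))
  expect_error(compare_arms(ms, ms), "opposite arms")
  ms2 <- make_tally(62, "ms", 1e4, 500, 450, 9000, 8500)
  expect_error(compare_arms(ms2, noms), "same entry-age")
})

test_that("participation arithmetic interpolates between the two expectations", {
  expect_equal(participation_scenario(20657, 16381, 0.5)$expected_deaths, 18519)
  full <- participation_scenario(20657, 16381, 1)
  expect_equal(full$expected_deaths, 16381)
  expect_equal(round(full$reduction_pct, 1), 20.7)
  expect_equal(participation_scenario(20657, 16381, 0)$expected_deaths, 20657)
  expect_error(participation_scenario(20657, 16381, 1.2), "participation")
  expect_error(participation_scenario(100, 200, 0.5), "exceed")
})

test_that("incremental round comparison emits the four decision quantities", {
  ms48 <- make_tally(48, "ms", 54000, 411, 397, 10740, 10309)
  noms48 <- make_tally(48, "no_ms", 54000, 733, 708, 19524, 18780)
  s48 <- compare_arms(ms48, noms48)
  cmp <- incremental_round_comparison(s48, s48)
  expect_equal(nrow(cmp), 3)
  expect_true(all(cmp[cmp$candidate == "diff",
                      c("pd_corr", "mse_per_pd_corr", "ly_corr")] == 0))
  ms70 <- make_tally(70, "ms", 47800, 554, 405, 4966, 3884)
  noms70 <- make_tally(70, "no_ms", 47800, 973, 725, 9134, 7291)
  s70 <- compare_arms(ms70, noms70)
  cmp2 <- incremental_round_comparison(s48, s70)
  expect_equal(cmp2$pd_corr[1:2], c(311, 320))
  expect_equal(cmp2$pd_corr[3], 9)
})

test_that("zero incidence propagates to zero benefit, not division errors", {
  d <- synth_demography(incidence = make_incidence(0, 0),
                        population = make_population(2000))
  sw <- sweep_ages(d, ages = c(50, 60), replicates = 1, master_seed = 1)
  expect_true(all(sw$pd == 0))
  expect_true(all(is.na(sw$mse_per_pd_corr)))
  expect_true(all(is.na(sw$pd_per_10k)))
  expect_true(is.na(attr(sw, "argmin_mse_per_pd")))
})

test_that("interval aggregation weights by screens, not by per-cohort ratios", {
  ms48 <- make_tally(48, "ms", 54000, 411, 397, 10740, 10309)
  noms48 <- make_tally(48, "no_ms", 54000, 733, 708, 19524, 18780)
  ms70 <- make_tally(70, "ms", 20000, 554, 405, 4966, 3884)
  noms70 <- make_tally(70, "no_ms", 20000, 973, 725, 9134, 7291)
  fake_sweep <- rbind(compare_arms(ms48, noms48),
                      compare_arms(ms70, noms70, n_women = 20000))
  agg <- aggregate_interval(fake_sweep, 48, 70)
  expect_equal(agg$pd_corr, 311 + 320)
  expect_equal(agg$mse, (54000 + 20000) * 10)
  expect_equal(agg$mse_per_pd_corr, agg$mse / agg$pd_corr)
  # not the mean of the two per-cohort ratios
  expect_false(isTRUE(all.equal(agg$mse_per_pd_corr,
                                mean(fake_sweep$mse_per_pd_corr))))
  expect_error(aggregate_interval(fake_sweep, 90, 95), "no cohorts")
})
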