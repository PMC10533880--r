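#' Screening policy parameters
#'
#' @param interval Years between screening examinations (biennial: 2).
#' @param follow_up Follow-up horizon, years.
#' @param cost_per_mse Cost of one mammography screening examination, EUR.
#' @param age_interval Two-element age interval of the program.
#' @return An object of class `screening_policy`; `screens_per_woman` is
#'   `follow_up / interval` (10 for the biennial 20-year design).
#' @export
screening_policy <- function(interval = 2, follow_up = 20, cost_per_mse = 88,
                             age_interval = c(40, 80)) {
  if (interval <= 0 || follow_up <= 0 || follow_up %% interval != 0) {
    stop("`follow_up` must be a positive multiple of `interval`", call. = FALSE)
  }
  if (cost_per_mse < 0) stop("`cost_per_mse` must be non-negative", call. = FALSE)
  structure(list(interval = interval, follow_up = follow_up,
                 screens_per_woman = follow_up / interval,
                 cost_per_mse = cost_per_mse,
                 age_interval = age_interval),
            class = "screening_policy")
}

ratio_or_na <- function(num, den) {
  if (!is.finite(den) || den <= 0) NA_real_ else num / den
}

#' Benefit and cost metrics comparing the two arms of one cohort
#'
#' Differences of the unscreened minus screened tallies give prevented deaths
#' (`pd` from expected lives lost, `pd_corr` after competing-event
#' correction) and life-years gained (`ly_corr`). These are set against the
#' number of screening examinations (`mse = screens_per_woman x n_women`)
#' and its cost. Ratios that are not estimable (no corrected prevented
#' deaths, or no life-years gained) are reported as `NA`, never as division
#' by zero.
#'
#' @param tally_ms,tally_noms `endpoint_tally` rows for the screened and
#'   unscreened arm of the same cohort.
#' @param n_women Women in the cohort (defaults to the tallies' value).
#' @param policy A [screening_policy()].
#' @return One-row `data.frame` of class `benefit_summary` with fields
#'   `entry_age`, `pd`, `pd_corr`, `mse`, `mse_per_pd_corr`,
#'   `cost_per_pd_corr`, `ly_corr`, `mse_per_ly_corr`, `cost_per_ly_corr`,
#'   `pd_per_10k`, `ly_per_10k`.
#' @export
compare_arms <- function(tally_ms, tally_noms, n_women = tally_ms$n_women,
                         policy = screening_policy()) {
  stopifnot(inherits(policy, "screening_policy"))
  if (tally_ms$entry_age != tally_noms$entry_age) {
    stop("tallies must come from the same entry-age cohort", call. = FALSE)
  }
  if (identical(tally_ms$arm, tally_noms$arm)) {
    stop("tallies must come from opposite arms", call. = FALSE)
  }
  pd <- tally_noms$ll - tally_ms$ll
  pd_corr <- tally_noms$ll_corr - tally_ms$ll_corr
  ly <- tally_noms$yll - tally_ms$yll
  ly_corr <- tally_noms$yll_corr - tally_ms$yll_corr
  mse <- policy$screens_per_woman * n_women
  mse_per_pd_corr <- ratio_or_na(mse, pd_corr)
  mse_per_ly_corr <- ratio_or_na(mse, ly_corr)
  structure(data.frame(
    entry_age = tally_ms$entry_age, n_women = n_women,
    pd = pd, pd_corr = pd_corr, mse = mse,
    mse_per_pd_corr = mse_per_pd_corr,
    cost_per_pd_corr = policy$cost_per_mse * mse_per_pd_corr,
    ly = ly, ly_corr = ly_corr,
    mse_per_ly_corr = mse_per_ly_corr,
    cost_per_ly_corr = policy$cost_per_mse * mse_per_ly_corr,
    pd_per_10k = if (is.na(mse_per_pd_corr)) NA_real_ else 1e4 / mse_per_pd_corr,
    ly_per_10k = if (is.na(mse_per_ly_corr)) NA_real_ else 1e4 / mse_per_ly_corr,
    stringsAsFactors = FALSE, row.names = NULL),
    class = c("benefit_summary", "data.frame"))
}

#' Sweep entry ages 40..80 and compare arms at each
#'
#' Runs the full microsimulation (both arms, all replicates) for every entry
#' age and compiles one [compare_arms()] summary per cohort. The attribute
#' `"tallies"` carries the aggregated per-cohort-arm endpoint tallies and
#' `"argmin_mse_per_pd"` the entry age minimizing screens per corrected
#' prevented death.
#'
#' @param demography A `demography` object covering all cohorts.
#' @param calibrations List with elements `ms` and `no_ms`, each an
#'   [arm_calibration()].
#' @param policy A [screening_policy()].
#' @param ages Entry ages to sweep (default 40 to 80 in steps of 2).
#' @param replicates Monte-Carlo replicates per cohort-arm.
#' @param master_seed Master seed for all random draws.
#' @param accrual_mode,met_offset Passed to [cohort_spec()].
#' @return `data.frame` of class `benefit_sweep`, one row per entry age.
#' @export
sweep_ages <- function(demography,
                       calibrations = list(ms = arm_calibration("ms"),
                                           no_ms = arm_calibration("no_ms")),
                       policy = screening_policy(),
                       ages = seq(40L, 80L, by = 2L),
                       replicates = 50L, master_seed = 1L,
                       accrual_mode = "across-rounds", met_offset = 28) {
  stopifnot(inherits(demography, "demography"))
  schedules <- list(ms = build_schedule(calibrations$ms),
                    no_ms = build_schedule(calibrations$no_ms))
  summaries <- vector("list", length(ages))
  tallies <- vector("list", 2L * length(ages))
  for (i in seq_along(ages)) {
    a <- ages[i]
    n_women <- cohort_n_women(demography$population, a)
    tally <- list()
    for (arm in c("ms", "no_ms")) {
      spec <- cohort_spec(a, arm, n_women, accrual_mode = accrual_mode,
                          met_offset = met_offset, replicates = replicates,
                          seed = master_seed)
      tally[[arm]] <- tryCatch(
        simulate_cohort_replicates(spec, schedules[[arm]], demography),
        error = function(e) stop(sprintf("cohort %d, arm %s: %s", a, arm,
                                         conditionMessage(e)), call. = FALSE))
    }
    summaries[[i]] <- compare_arms(tally$ms, tally$no_ms, n_women, policy)
    tallies[[2L * i - 1L]] <- tally$ms
    tallies[[2L * i]] <- tally$no_ms
  }
  out <- do.call(rbind, summaries)
  all_tallies <- do.call(rbind, lapply(tallies, function(t) {
    attr(t, "replicates") <- NULL
    t
  }))
  finite_ratio <- is.finite(out$mse_per_pd_corr)
  attr(out, "tallies") <- all_tallies
  attr(out, "argmin_mse_per_pd") <-
    if (any(finite_ratio)) out$entry_age[which.min(out$mse_per_pd_corr)] else NA_integer_
  class(out) <- c("benefit_sweep", "data.frame")
  out
}

#' Aggregate a sweep over an age interval
#'
#' Sums prevented deaths, life-years and screening examinations over the
#' cohorts inside `[lo, hi]` before forming ratios, i.e. the aggregate is
#' MSE-weighted ("sum / weighted means" semantics), not an average of
#' per-cohort ratios.
#'
#' @param sweep A [sweep_ages()] result.
#' @param lo,hi Inclusive entry-age bounds of the interval.
#' @param policy The [screening_policy()] used for the sweep.
#' @return One-row `benefit_summary` labelled with the interval.
#' @export
aggregate_interval <- function(sweep, lo, hi, policy = screening_policy()) {
  rows <- sweep[sweep$entry_age >= lo & sweep$entry_age <= hi, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no cohorts inside the interval", call. = FALSE)
  pd <- sum(rows$pd); pd_corr <- sum(rows$pd_corr)
  ly <- sum(rows$ly); ly_corr <- sum(rows$ly_corr)
  mse <- sum(rows$mse)
  mse_per_pd_corr <- ratio_or_na(mse, pd_corr)
  mse_per_ly_corr <- ratio_or_na(mse, ly_corr)
  out <- data.frame(
    age_interval = sprintf("%d-%d", lo, hi),
    n_women = sum(rows$n_women),
    pd = pd, pd_corr = pd_corr, mse = mse,
    mse_per_pd_corr = mse_per_pd_corr,
    cost_per_pd_corr = policy$cost_per_mse * mse_per_pd_corr,
    ly = ly, ly_corr = ly_corr,
    mse_per_ly_corr = mse_per_ly_corr,
    cost_per_ly_corr = policy$cost_per_mse * mse_per_ly_corr,
    pd_per_10k = if (is.na(mse_per_pd_corr)) NA_real_ else 1e4 / mse_per_pd_corr,
    ly_per_10k = if (is.na(mse_per_ly_corr)) NA_real_ else 1e4 / mse_per_ly_corr,
    stringsAsFactors = FALSE)
  class(out) <- c("benefit_summary", "data.frame")
  out
}

#' Expected breast-cancer deaths under partial screening participation
#'
#' Linear interpolation between the expected deaths without any screening and
#' with full participation.
#'
#' @param deaths_without_ms Expected deaths at participation 0.
#' @param deaths_with_full_ms Expected deaths at participation 1; must not
#'   exceed `deaths_without_ms`.
#' @param participation Participation fraction in \[0, 1\].
#' @return List with `expected_deaths` at the given participation and
#'   `reduction_pct`, the full-participation mortality reduction in percent.
#' @examples
#' participation_scenario(20657, 16381, 0.5)$expected_deaths # 18519
#' @export
participation_scenario <- function(deaths_without_ms, deaths_with_full_ms,
                                   participation) {
  if (!is.numeric(participation) || any(participation < 0) || any(participation > 1)) {
    stop("`participation` must lie in [0, 1]", call. = FALSE)
  }
  if (deaths_with_full_ms > deaths_without_ms) {
    stop("`deaths_with_full_ms` must not exceed `deaths_without_ms`", call. = FALSE)
  }
  expected <- deaths_without_ms -
    participation * (deaths_without_ms - deaths_with_full_ms)
  list(expected_deaths = expected,
       reduction_pct = 100 * (deaths_without_ms - deaths_with_full_ms) /
         deaths_without_ms)
}

#' Side-by-side decision quantities for an additional screening round
#'
#' When an eleventh screening examination is considered — starting two years
#' earlier or extending two years later — four quantities decide between the
#' candidate cohorts: corrected prevented deaths, screens (and cost) per
#' prevented death, life-years gained, and screens (and cost) per life-year.
#'
#' @param summary_lo,summary_hi [compare_arms()] rows for the lower and upper
#'   candidate entry ages.
#' @return `data.frame` with one row per candidate plus a `diff` row
#'   (upper minus lower); `NA` ratios propagate as `NA`.
#' @export
incremental_round_comparison <- function(summary_lo, summary_hi) {
  stopifnot(inherits(summary_lo, "benefit_summary"),
            inherits(summary_hi, "benefit_summary"))
  cols <- c("pd_corr", "mse_per_pd_corr", "cost_per_pd_corr",
            "ly_corr", "mse_per_ly_corr", "cost_per_ly_corr")
  lo <- summary_lo[, cols, drop = FALSE]
  hi <- summary_hi[, cols, drop = FALSE]
  out <- rbind(lo, hi, hi - lo)
  out <- cbind(candidate = c(
    as.character(summary_lo$entry_age), as.character(summary_hi$entry_age),
    "diff"), out)
  rownames(out) <- NULL
  out
}
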