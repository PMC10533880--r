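#' Specification of one simulated cohort-arm
#'
#' Describes one entry-age cohort in one arm: the number of women in the
#' 2-year entry band, accrual of breast-cancer diagnoses, follow-up horizon,
#' metastasis backdating, replicate count and master seed.
#'
#' Accrual modes: under `"across-rounds"` (default) diagnoses accrue
#' uniformly over the 20-year screening period — each patient is diagnosed at
#' her attained age and followed 20 years from diagnosis by the tumor
#' survival function, while competing mortality always acts at her attained
#' age. Under `"at-entry"` the same expected number of diagnoses all occur at
#' the entry age.
#'
#' @param entry_age Age at the first screening examination, years.
#' @param arm `"ms"` (screened) or `"no_ms"` (unscreened).
#' @param n_women Women in the 2-year entry cohort.
#' @param accrual_mode `"across-rounds"` or `"at-entry"`.
#' @param follow_up Follow-up horizon, years (fixed design: 20).
#' @param met_offset Months between metastasis and tumor-related death
#'   (default 28).
#' @param replicates Number of Monte-Carlo replicates (default 50).
#' @param seed Master seed; per-replicate generators are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(entry_age, arm = c("ms", "no_ms"), n_women,
                        accrual_mode = c("across-rounds", "at-entry"),
                        follow_up = 20L, met_offset = 28,
                        replicates = 50L, seed = 1L) {
  arm <- match.arg(arm)
  accrual_mode <- match.arg(accrual_mode)
  if (!is.numeric(entry_age) || length(entry_age) != 1L || entry_age < 0) {
    stop("`entry_age` must be a single non-negative age", call. = FALSE)
  }
  if (!is.numeric(n_women) || length(n_women) != 1L || n_women < 0) {
    stop("`n_women` must be a single non-negative count", call. = FALSE)
  }
  if (follow_up != 20L) {
    stop("`follow_up` is fixed at 20 years in this design", call. = FALSE)
  }
  if (!(met_offset > 0 && met_offset < follow_up * 12)) {
    stop("`met_offset` must lie in (0, 240) months", call. = FALSE)
  }
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  structure(list(entry_age = as.integer(entry_age), arm = arm,
                 n_women = n_women, accrual_mode = accrual_mode,
                 follow_up = as.integer(follow_up), met_offset = met_offset,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "cohort_spec")
}

# Deterministic per-(cohort, arm, replicate) seed below 2^31, so arms and
# replicates are independently reproducible from one master seed.
derive_seed <- function(master, entry_age, arm, replicate) {
  arm_id <- if (identical(arm, "ms")) 1 else 2
  s <- (as.double(master) * 1000003 + entry_age * 8191 +
          arm_id * 524287 + replicate * 7919) %% 2147483629
  as.integer(s + 1)
}

#' Draw one event time from a schedule of annual hazards
#'
#' Stepwise over the follow-up years: year k is chosen with probability
#' (prod of prior annual survivals) x h_k, and the date within the year is
#' uniform. With probability prod(1 - h) no event occurs within the horizon
#' and `NA` is returned. Uses R's global random number generator.
#'
#' @param annual_hazards Conditional event probabilities per follow-up year,
#'   each in \[0, 1\].
#' @param n Number of independent draws.
#' @return Numeric vector of length `n`: months from start in
#'   `(0, 12 * length(annual_hazards)]`, or `NA` for no event.
#' @export
draw_event_year <- function(annual_hazards, n = 1L) {
  if (!is.numeric(annual_hazards) || any(!is.finite(annual_hazards)) ||
      any(annual_hazards < 0) || any(annual_hazards > 1)) {
    stop("`annual_hazards` must be probabilities in [0, 1]", call. = FALSE)
  }
  k <- length(annual_hazards)
  surv <- cumprod(1 - annual_hazards)
  p_year <- c(1, surv[-k]) * annual_hazards
  f <- cumsum(p_year)
  u <- stats::runif(n)
  yr <- findInterval(u, f, left.open = TRUE) + 1L
  months <- ifelse(yr > k, NA_real_, (yr - 1) * 12 + stats::runif(n) * 12)
  months
}

#' Classify a trajectory into the six patient-relevant endpoints
#'
#' Endpoint taxonomy over 20 years of follow-up after breast-cancer
#' diagnosis: E1 no event; E2 tumor-independent death only; destined tumor
#' deaths (E3) split by the sequence of events relative to metastasis (MET,
#' backdated `met_offset` months before the would-be tumor death): E4 tumor
#' death is the first event, E5 tumor-independent death strikes before MET,
#' E6 tumor-independent death strikes after MET. Exact ties between the two
#' death times resolve to the tumor-independent event.
#'
#' @param t_bc_death Months from diagnosis to destined tumor-related death,
#'   `NA` if none within the horizon. Vectorized.
#' @param t_other_death Months from diagnosis to tumor-independent death,
#'   `NA` if none within the horizon.
#' @param met_offset Months between MET and tumor-related death.
#' @return Character vector of `"E1"`, `"E2"`, `"E4"`, `"E5"`, `"E6"`.
#' @export
classify_endpoint <- function(t_bc_death, t_other_death, met_offset = 28) {
  if (any(t_bc_death <= 0, na.rm = TRUE) || any(t_other_death <= 0, na.rm = TRUE)) {
    stop("event times must be positive (months from diagnosis)", call. = FALSE)
  }
  t_met <- pmax(t_bc_death - met_offset, 0)
  ifelse(is.na(t_bc_death),
         ifelse(is.na(t_other_death), "E1", "E2"),
         ifelse(is.na(t_other_death) | t_bc_death < t_other_death, "E4",
                ifelse(t_other_death < t_met, "E5", "E6")))
}

# Annual death probabilities q over `horizon` years starting at integer age
# `start_age`. Ages past the table's closing row keep q = 1 (the table is
# closed); ages below its start are a coverage error.
lifetable_hazards <- function(life_table, start_age, horizon) {
  ages <- start_age + 0:(horizon - 1L)
  lo <- min(life_table$age); hi <- max(life_table$age)
  if (start_age < lo) {
    stop(sprintf("life table starts at age %d; needed age %d", lo, start_age),
         call. = FALSE)
  }
  q <- numeric(length(ages))
  inside <- ages <= hi
  q[inside] <- life_table$q[match(ages[inside], life_table$age)]
  if (any(!inside)) {
    if (life_table$q[life_table$age == hi] < 1) {
      stop(sprintf(
        "life table ends at age %d without closing (q < 1); cannot extend to age %d",
        hi, max(ages)), call. = FALSE)
    }
    q[!inside] <- 1
  }
  q
}

residual_expectancy_at <- function(life_table, age) {
  age <- pmin(pmax(floor(age), min(life_table$age)), max(life_table$age))
  life_table$e[match(age, life_table$age)]
}

# Expected diagnoses per accrual year: population of the 2-year entry band
# times the incidence rate at each attained age, depletion ignored.
expected_diagnoses <- function(spec, incidence) {
  ages <- spec$entry_age + 0:(spec$follow_up - 1L)
  if (min(ages) < min(incidence$age) || max(ages) > max(incidence$age)) {
    stop(sprintf("incidence table must cover ages %d..%d for entry age %d",
                 min(ages), max(ages), spec$entry_age), call. = FALSE)
  }
  rate <- incidence$rate_per_100k[match(ages, incidence$age)]
  data.frame(age = ages, expected = spec$n_women * rate / 1e5)
}

# Stochastic rounding preserving the expectation.
round_stochastic <- function(x) {
  fl <- floor(x)
  fl + (stats::runif(length(x)) < (x - fl))
}

#' Simulate one cohort-arm for one replicate
#'
#' Draws the number of breast-cancer diagnoses from the incidence and cohort
#' size, then for every patient independently draws a destined tumor-related
#' death time from the arm's hazard schedule and a tumor-independent death
#' time from the life table at her attained ages; classifies endpoints and
#' tallies lives lost (LL) and years of life lost (YLL), each with and
#' without correction for competing-event preemption. Years of life lost per
#' tumor death are the residual life expectancy at the age of the (destined
#' or realized) tumor death.
#'
#' The caller controls the random number generator state (see
#' [simulate_cohort_replicates()] for the seeded multi-replicate driver).
#'
#' @param spec A [cohort_spec()].
#' @param schedule A [build_schedule()] result for the cohort's arm.
#' @param life_table,incidence Demography tables covering the cohort's ages.
#' @return One-row `data.frame` of class `endpoint_tally`: `entry_age`,
#'   `arm`, `n_women`, `n_bc`, endpoint fractions `e1`..`e6` (of breast
#'   cancer patients), `ll`, `ll_corr`, `yll`, `yll_corr`.
#' @export
simulate_cohort <- function(spec, schedule, life_table, incidence) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(schedule, "survival_schedule"))
  if (schedule$arm != spec$arm) {
    stop(sprintf("schedule is calibrated for arm '%s' but spec is arm '%s'",
                 schedule$arm, spec$arm), call. = FALSE)
  }
  acc <- expected_diagnoses(spec, incidence)
  n_by_age <- round_stochastic(acc$expected)
  diag_age <- if (spec$accrual_mode == "at-entry") {
    rep(spec$entry_age, sum(n_by_age))
  } else {
    rep(acc$age, n_by_age)
  }
  n_bc <- length(diag_age)

  counts <- c(E1 = 0, E2 = 0, E4 = 0, E5 = 0, E6 = 0)
  yll <- 0; yll_corr <- 0
  for (a in unique(diag_age)) {
    m <- sum(diag_age == a)
    t_bc <- draw_event_year(schedule$annual_hazard, m)
    q <- lifetable_hazards(life_table, a, spec$follow_up)
    t_other <- draw_event_year(q, m)
    ep <- classify_endpoint(t_bc, t_other, spec$met_offset)
    tab <- table(factor(ep, levels = names(counts)))
    counts <- counts + as.numeric(tab)
    destined <- !is.na(t_bc)
    if (any(destined)) {
      e_at <- residual_expectancy_at(life_table, a + t_bc[destined] / 12)
      yll <- yll + sum(e_at)
      yll_corr <- yll_corr + sum(e_at[ep[destined] == "E4"])
    }
  }
  e3_count <- counts[["E4"]] + counts[["E5"]] + counts[["E6"]]
  frac <- if (n_bc > 0) counts / n_bc else counts * NA_real_
  structure(data.frame(
    entry_age = spec$entry_age, arm = spec$arm,
    n_women = spec$n_women, n_bc = n_bc,
    e1 = unname(frac[["E1"]]), e2 = unname(frac[["E2"]]),
    e3 = if (n_bc > 0) e3_count / n_bc else NA_real_,
    e4 = unname(frac[["E4"]]), e5 = unname(frac[["E5"]]),
    e6 = unname(frac[["E6"]]),
    ll = e3_count, ll_corr = counts[["E4"]],
    yll = yll, yll_corr = yll_corr,
    stringsAsFactors = FALSE, row.names = NULL),
    class = c("endpoint_tally", "data.frame"))
}

#' Run all replicates of one cohort-arm and average
#'
#' Seeds a fresh generator per replicate (derived from the master seed, the
#' entry age, the arm and the replicate index) and averages the replicate
#' tallies with [aggregate_replicates()].
#'
#' @param spec A [cohort_spec()].
#' @param schedule Matching [build_schedule()] result.
#' @param demography A `demography` object (or pass `life_table` and
#'   `incidence` explicitly).
#' @param life_table,incidence Overrides for the component tables.
#' @return The aggregated `endpoint_tally` (see [aggregate_replicates()]),
#'   with the per-replicate tallies in attribute `"replicates"`.
#' @export
simulate_cohort_replicates <- function(spec, schedule, demography = NULL,
                                       life_table = demography$life_table,
                                       incidence = demography$incidence) {
  tallies <- vector("list", spec$replicates)
  for (r in seq_len(spec$replicates)) {
    set.seed(derive_seed(spec$seed, spec$entry_age, spec$arm, r))
    tallies[[r]] <- simulate_cohort(spec, schedule, life_table, incidence)
  }
  aggregate_replicates(tallies)
}

#' Average endpoint tallies over replicates
#'
#' Element-wise means over replicate tallies, with Monte-Carlo standard
#' errors of the mean (`se_` columns) for every numeric field.
#'
#' @param tallies List of `endpoint_tally` rows (or a `data.frame` of them).
#' @return One-row `endpoint_tally` of means with `se_*` columns appended and
#'   the replicate table as attribute `"replicates"`.
#' @export
aggregate_replicates <- function(tallies) {
  if (is.data.frame(tallies)) tallies <- list(tallies)
  if (length(tallies) == 0L) stop("no replicates to aggregate", call. = FALSE)
  reps <- do.call(rbind, tallies)
  if (length(unique(reps$entry_age)) != 1L || length(unique(reps$arm)) != 1L) {
    stop("replicates must come from a single cohort and arm", call. = FALSE)
  }
  num_cols <- setdiff(names(reps)[vapply(reps, is.numeric, logical(1))],
                      c("entry_age", "n_women"))
  out <- reps[1, , drop = FALSE]
  n <- nrow(reps)
  for (cn in num_cols) {
    out[[cn]] <- mean(reps[[cn]])
    out[[paste0("se_", cn)]] <- if (n > 1) stats::sd(reps[[cn]]) / sqrt(n) else NA_real_
  }
  rownames(out) <- NULL
  attr(out, "replicates") <- reps
  class(out) <- c("endpoint_tally", "data.frame")
  out
}

#' Number of women in a 2-year entry cohort
#'
#' @param population A `population_table`.
#' @param entry_age First age of the 2-year band.
#' @return Sum of the counts at `entry_age` and `entry_age + 1`.
#' @export
cohort_n_women <- function(population, entry_age) {
  idx <- match(c(entry_age, entry_age + 1L), population$age)
  if (any(is.na(idx))) {
    stop(sprintf("population table does not cover ages %d-%d",
                 entry_age, entry_age + 1L), call. = FALSE)
  }
  sum(population$count[idx])
}
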