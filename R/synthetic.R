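#' Synthetic female life table with Gompertz-Makeham mortality
#'
#' Generates a single-year-of-age life table `(age, q, e)` from a
#' Gompertz-Makeham hazard \eqn{\mu(a) = c + A e^{b a}} with annual death
#' probability \eqn{q(a) = 1 - e^{-\mu(a)}}. The residual life expectancy
#' column `e` is computed from `q` by standard life-table accounting assuming
#' deaths occur mid-year, so the two columns are mutually consistent by
#' construction. The table is closed at `max_age` by setting `q = 1` there.
#'
#' The default coefficients are fixed calibration constants chosen so that
#' 20-year all-cause survival is approximately 94% from age 40, 75% from age
#' 60 and 2% from age 80 — the pattern of a current Western European female
#' mortality table. They are deterministic; the generator uses no random
#' numbers.
#'
#' @param makeham_offset Age-independent hazard component c, per year
#'   (accidents/background). Non-negative.
#' @param gompertz_scale Gompertz scale A, per year. Non-negative.
#' @param gompertz_slope Gompertz slope b, per year of age. Non-negative.
#' @param min_age,max_age Closed age range of the table; `max_age >= 100`.
#' @return A `data.frame` of class `life_table` with columns `age`, `q`, `e`.
#' @examples
#' lt <- make_life_table()
#' head(lt)
#' @export
make_life_table <- function(makeham_offset = 0.00234,
                            gompertz_scale = 5.76e-7,
                            gompertz_slope = 0.1388,
                            min_age = 40L, max_age = 105L) {
  for (nm in c("makeham_offset", "gompertz_scale", "gompertz_slope")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("`%s` must be a single non-negative number", nm), call. = FALSE)
    }
  }
  if (max_age < 100) stop("`max_age` must be at least 100", call. = FALSE)
  if (min_age >= max_age) stop("`min_age` must be below `max_age`", call. = FALSE)
  age <- as.integer(min_age):as.integer(max_age)
  mu <- makeham_offset + gompertz_scale * exp(gompertz_slope * age)
  q <- 1 - exp(-mu)
  q[length(q)] <- 1 # close the table: nobody survives past max_age
  e <- life_expectancy_from_q(q)
  structure(data.frame(age = age, q = q, e = e),
            class = c("life_table", "data.frame"))
}

#' Residual life expectancy from annual death probabilities
#'
#' Backward recursion `e_x = (1 - q_x) (1 + e_{x+1}) + q_x / 2`, i.e. deaths
#' are spread uniformly over the year of death. Beyond the last tabulated age
#' the remaining expectancy is taken as zero, which is exact when the table
#' is closed with `q = 1` at its last age.
#'
#' @param q Vector of annual death probabilities for consecutive ages.
#' @return Vector of residual life expectancies, in years.
#' @export
life_expectancy_from_q <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0) || any(q > 1)) {
    stop("`q` must be probabilities in [0, 1]", call. = FALSE)
  }
  n <- length(q)
  e <- numeric(n)
  e[n] <- (1 - q[n]) * 1 + q[n] * 0.5
  if (n > 1L) {
    for (i in (n - 1L):1L) e[i] <- (1 - q[i]) * (1 + e[i + 1L]) + q[i] * 0.5
  }
  e
}

#' Synthetic breast-cancer incidence curve
#'
#' Logistic age-incidence curve rising from `base_rate` around age 40 to
#' `plateau_rate` in the mid-70s, the qualitative shape of female invasive
#' breast-cancer incidence in Western registries. Default constants are
#' calibrated once so that cohorts entering at 50-69 accumulate roughly 57
#' diagnoses per 1000 women over 20 years of follow-up. Deterministic.
#'
#' @param base_rate Incidence near age 40, per 100,000 woman-years.
#' @param plateau_rate Plateau incidence at high ages, per 100,000
#'   woman-years; must be `>= base_rate`.
#' @param inflection_age Age at the logistic midpoint, years.
#' @param width Logistic width, years.
#' @param min_age,max_age Age range of the table.
#' @return A `data.frame` of class `incidence_table` with columns `age`,
#'   `rate_per_100k`.
#' @export
make_incidence <- function(base_rate = 100, plateau_rate = 310,
                           inflection_age = 55, width = 5,
                           min_age = 40L, max_age = 105L) {
  if (!is.numeric(base_rate) || base_rate < 0) {
    stop("`base_rate` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(plateau_rate) || plateau_rate < base_rate) {
    stop("`plateau_rate` must be >= `base_rate`", call. = FALSE)
  }
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  age <- as.integer(min_age):as.integer(max_age)
  rate <- base_rate + (plateau_rate - base_rate) *
    stats::plogis((age - inflection_age) / width)
  structure(data.frame(age = age, rate_per_100k = rate),
            class = c("incidence_table", "data.frame"))
}

#' Synthetic female population by single year of age
#'
#' A flat-topped pyramid: approximately `base_count` women per single year of
#' age through mid-life, declining logistically at high ages as cohort
#' survival falls. The default scale is chosen so a 2-year entry cohort holds
#' roughly 54,000 women, the size of the modeled screening populations.
#' Deterministic.
#'
#' @param base_count Women per single year of age before the decline.
#' @param decline_age Age at which the count has halved, years.
#' @param decline_width Logistic width of the decline, years.
#' @param min_age,max_age Age range of the table.
#' @return A `data.frame` of class `population_table` with columns `age`,
#'   `count`.
#' @export
make_population <- function(base_count = 27000, decline_age = 82,
                            decline_width = 6, min_age = 40L, max_age = 105L) {
  if (!is.numeric(base_count) || base_count < 0) {
    stop("`base_count` must be non-negative", call. = FALSE)
  }
  if (decline_width <= 0) stop("`decline_width` must be positive", call. = FALSE)
  age <- as.integer(min_age):as.integer(max_age)
  count <- as.integer(round(base_count * stats::plogis((decline_age - age) / decline_width)))
  structure(data.frame(age = age, count = count),
            class = c("population_table", "data.frame"))
}

#' Bundle the three demography tables
#'
#' @param life_table,incidence,population The three component tables; the
#'   synthetic defaults are used where omitted. Ages are aligned to the
#'   common (intersection) range across the three tables.
#' @return An object of class `demography` with elements `life_table`,
#'   `incidence`, `population`.
#' @export
synth_demography <- function(life_table = make_life_table(),
                             incidence = make_incidence(),
                             population = make_population()) {
  lo <- max(min(life_table$age), min(incidence$age), min(population$age))
  hi <- min(max(life_table$age), max(incidence$age), max(population$age))
  if (lo > hi) stop("demography tables have no common age range", call. = FALSE)
  trim <- function(d) d[d$age >= lo & d$age <= hi, , drop = FALSE]
  structure(list(life_table = trim(life_table),
                 incidence = trim(incidence),
                 population = trim(population)),
            class = "demography")
}

#' Write demography tables to a directory of CSV files
#'
#' One fixed dialect is used throughout: comma-separated, header row, dot
#' decimal. Files are `lifetable.csv` (age,q,e), `incidence.csv`
#' (age,rate_per_100k) and `population.csv` (age,count). Real supplementary
#' tables must be exported to this dialect to be loadable.
#'
#' @param demography A [synth_demography()] object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_demography <- function(demography, dir) {
  stopifnot(inherits(demography, "demography"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(lifetable = file.path(dir, "lifetable.csv"),
             incidence = file.path(dir, "incidence.csv"),
             population = file.path(dir, "population.csv"))
  utils::write.csv(demography$life_table, paths[["lifetable"]], row.names = FALSE)
  utils::write.csv(demography$incidence, paths[["incidence"]], row.names = FALSE)
  utils::write.csv(demography$population, paths[["population"]], row.names = FALSE)
  invisible(paths)
}

stop_parse <- function(file, msg, row = NULL) {
  where <- if (is.null(row)) basename(file) else sprintf("%s, row %d", basename(file), row)
  stop(sprintf("%s: %s", where, msg), call. = FALSE)
}

read_table_checked <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop(sprintf("demography file not found: %s", path), call. = FALSE)
  }
  d <- utils::read.csv(path)
  missing <- setdiff(required_cols, names(d))
  if (length(missing)) {
    stop_parse(path, sprintf("missing required column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  if (nrow(d) == 0L) stop_parse(path, "table is empty")
  if (any(!is.finite(d$age)) || any(d$age != round(d$age))) {
    stop_parse(path, "`age` must be integer years",
               row = which(!is.finite(d$age) | d$age != round(d$age))[1])
  }
  if (is.unsorted(d$age, strictly = TRUE)) {
    stop_parse(path, "`age` must be strictly increasing")
  }
  gaps <- which(diff(d$age) != 1)
  if (length(gaps)) {
    stop_parse(path, sprintf("ages must be contiguous; gap after age %d", d$age[gaps[1]]),
               row = gaps[1])
  }
  d
}

#' Load demography tables from CSV files
#'
#' Reads and validates the three tables written by [write_demography()] (or
#' real supplementary tables exported to the same dialect), then aligns them
#' to their common age range.
#'
#' @param path_lifetable,path_incidence,path_population File paths.
#' @return A validated `demography` object.
#' @export
load_demography <- function(path_lifetable, path_incidence, path_population) {
  lt <- read_table_checked(path_lifetable, c("age", "q", "e"))
  bad_q <- which(!is.finite(lt$q) | lt$q < 0 | lt$q > 1)
  if (length(bad_q)) {
    stop_parse(path_lifetable,
               sprintf("`q` must lie in [0, 1]; got %g at age %d",
                       lt$q[bad_q[1]], lt$age[bad_q[1]]), row = bad_q[1])
  }
  bad_e <- which(!is.finite(lt$e) | lt$e < 0)
  if (length(bad_e)) {
    stop_parse(path_lifetable, sprintf("`e` must be non-negative at age %d",
                                       lt$age[bad_e[1]]), row = bad_e[1])
  }
  inc <- read_table_checked(path_incidence, c("age", "rate_per_100k"))
  bad_r <- which(!is.finite(inc$rate_per_100k) | inc$rate_per_100k < 0)
  if (length(bad_r)) {
    stop_parse(path_incidence, sprintf("`rate_per_100k` must be non-negative at age %d",
                                       inc$age[bad_r[1]]), row = bad_r[1])
  }
  pop <- read_table_checked(path_population, c("age", "count"))
  bad_c <- which(!is.finite(pop$count) | pop$count < 0)
  if (length(bad_c)) {
    stop_parse(path_population, sprintf("`count` must be non-negative at age %d",
                                        pop$age[bad_c[1]]), row = bad_c[1])
  }
  class(lt) <- c("life_table", "data.frame")
  class(inc) <- c("incidence_table", "data.frame")
  class(pop) <- c("population_table", "data.frame")
  synth_demography(life_table = lt, incidence = inc, population = pop)
}
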