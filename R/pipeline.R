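#' Run configuration for an end-to-end screening simulation
#'
#' Collects every tunable of the pipeline with the model's reference
#' defaults: biennial screening over 20 years of follow-up, metastasis
#' backdated 28 months before tumor death, 80% of incident cancers detected
#' by regular screening examinations (reported, not entering the survival
#' math, which is calibrated on the effective diameters), 88 EUR per
#' examination, 50 replicates, entry ages 40 to 80 in 2-year steps.
#'
#' Demography comes either from three CSV paths (`demography_paths`) or from
#' the synthetic generators (`synth_params`, passed to [make_life_table()],
#' [make_incidence()], [make_population()]). Exactly one source must be
#' given.
#'
#' @param demography_paths Named list/vector with `lifetable`, `incidence`,
#'   `population` CSV paths, or `NULL`.
#' @param synth_params List with optional elements `life_table`, `incidence`,
#'   `population`, each a list of generator arguments; an empty list uses all
#'   defaults. `NULL` disables synthesis.
#' @param master_seed Integer master seed.
#' @param replicates Replicates per cohort-arm.
#' @param ages Entry ages to sweep.
#' @param interval,cost_per_mse,follow_up Screening policy.
#' @param met_offset Months from metastasis to tumor death.
#' @param detection_fraction Fraction of cancers found by regular screening
#'   within the program (reporting only).
#' @param accrual_mode `"across-rounds"` or `"at-entry"`.
#' @param arms Arm calibrations: list with `ms` and `no_ms` lists holding
#'   `effective_td`, `s15`, `s20`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(demography_paths = NULL,
                       synth_params = list(),
                       master_seed = 1L,
                       replicates = 50L,
                       ages = seq(40L, 80L, by = 2L),
                       interval = 2,
                       cost_per_mse = 88,
                       follow_up = 20L,
                       met_offset = 28,
                       detection_fraction = 0.80,
                       accrual_mode = "across-rounds",
                       arms = list(
                         ms = list(effective_td = 16, s15 = 0.86, s20 = 0.819),
                         no_ms = list(effective_td = 22.7, s15 = 0.76, s20 = 0.679))) {
  if (is.null(demography_paths) && is.null(synth_params)) {
    stop("configuration error: provide `demography_paths` or `synth_params`",
         call. = FALSE)
  }
  if (!is.null(demography_paths)) {
    need <- c("lifetable", "incidence", "population")
    if (!all(need %in% names(demography_paths))) {
      stop("`demography_paths` must name lifetable, incidence and population files",
           call. = FALSE)
    }
  }
  if (detection_fraction <= 0 || detection_fraction > 1) {
    stop("`detection_fraction` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(demography_paths = demography_paths,
                 synth_params = synth_params,
                 master_seed = as.integer(master_seed),
                 replicates = as.integer(replicates),
                 ages = as.integer(ages),
                 interval = interval, cost_per_mse = cost_per_mse,
                 follow_up = as.integer(follow_up), met_offset = met_offset,
                 detection_fraction = detection_fraction,
                 accrual_mode = accrual_mode, arms = arms),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' JSON round-trip: `write_run_config()` then `read_run_config()` restores a
#' configuration equal to the original.
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `read_run_config()` returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$ages <- as.integer(raw$ages)
  if (!is.null(raw$demography_paths)) raw$demography_paths <- as.list(raw$demography_paths)
  if (!is.null(raw$synth_params)) {
    raw$synth_params <- lapply(raw$synth_params, as.list)
  }
  if (is.null(raw$synth_params) && is.null(raw$demography_paths)) {
    stop("configuration error: no demography source in file", call. = FALSE)
  }
  do.call(run_config, raw)
}

config_demography <- function(config) {
  if (!is.null(config$demography_paths)) {
    p <- config$demography_paths
    load_demography(p$lifetable, p$incidence, p$population)
  } else {
    sp <- config$synth_params
    synth_demography(
      life_table = do.call(make_life_table, as.list(sp$life_table)),
      incidence = do.call(make_incidence, as.list(sp$incidence)),
      population = do.call(make_population, as.list(sp$population)))
  }
}

config_calibrations <- function(config) {
  list(ms = do.call(arm_calibration, c(list(arm = "ms"), config$arms$ms)),
       no_ms = do.call(arm_calibration, c(list(arm = "no_ms"), config$arms$no_ms)))
}

#' Run the full screening-benefit pipeline
#'
#' Builds (or loads) demography, sweeps all configured entry-age cohorts in
#' both arms, and writes the tabular outputs to `out_dir`:
#' `tables2_3.csv` (per-cohort-arm endpoint distribution and LL/YLL, in
#' percent, with Monte-Carlo standard errors), `table4.csv` (benefit and cost
#' summaries), `endpoints_by_age.csv` (unscreened-arm endpoint distribution
#' by age, plot-ready), `mse_per_pd_by_age.csv` and `mse_per_ly_by_age.csv`
#' (screens per prevented death / per life-year by age), a `config.json`
#' snapshot and `log.txt`. Outputs are deterministic given the master seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the `sweep` result, the `tallies` and the
#'   output directory.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  log_lines <- c(sprintf("run started (seed %d, %d replicates, %d cohorts)",
                         config$master_seed, config$replicates,
                         length(config$ages)))
  demography <- config_demography(config)
  policy <- screening_policy(interval = config$interval,
                             follow_up = config$follow_up,
                             cost_per_mse = config$cost_per_mse,
                             age_interval = range(config$ages))
  sweep <- sweep_ages(demography,
                      calibrations = config_calibrations(config),
                      policy = policy, ages = config$ages,
                      replicates = config$replicates,
                      master_seed = config$master_seed,
                      accrual_mode = config$accrual_mode,
                      met_offset = config$met_offset)
  tallies <- attr(sweep, "tallies")
  for (r in seq_len(nrow(tallies))) {
    log_lines <- c(log_lines, sprintf(
      "cohort %d arm %-5s: replicate seeds %s..%s",
      tallies$entry_age[r], tallies$arm[r],
      derive_seed(config$master_seed, tallies$entry_age[r], tallies$arm[r], 1L),
      derive_seed(config$master_seed, tallies$entry_age[r], tallies$arm[r],
                  config$replicates)))
  }

  t23 <- tallies
  for (cn in c("e1", "e2", "e3", "e4", "e5", "e6",
               grep("^se_e[1-6]$", names(t23), value = TRUE))) {
    t23[[cn]] <- 100 * t23[[cn]]
  }
  pct <- grepl("^(se_)?e[1-6]$", names(t23))
  names(t23)[pct] <- paste0(names(t23)[pct], "_pct")
  write_num_csv(t23, file.path(out_dir, "tables2_3.csv"))
  write_num_csv(as.data.frame(sweep), file.path(out_dir, "table4.csv"))

  noms <- t23[t23$arm == "no_ms",
              c("entry_age", paste0("e", 1:6, "_pct")), drop = FALSE]
  write_num_csv(noms, file.path(out_dir, "endpoints_by_age.csv"))
  write_num_csv(data.frame(entry_age = sweep$entry_age,
                           mse_per_pd = ifelse(sweep$pd > 0, sweep$mse / sweep$pd, NA),
                           mse_per_pd_corr = sweep$mse_per_pd_corr),
                file.path(out_dir, "mse_per_pd_by_age.csv"))
  write_num_csv(data.frame(entry_age = sweep$entry_age,
                           mse_per_ly_corr = sweep$mse_per_ly_corr),
                file.path(out_dir, "mse_per_ly_by_age.csv"))
  write_run_config(config, file.path(out_dir, "config.json"))
  log_lines <- c(log_lines, sprintf(
    "minimum screens per corrected prevented death at entry age %s",
    attr(sweep, "argmin_mse_per_pd")))
  writeLines(log_lines, log_path)
  invisible(list(sweep = sweep, tallies = tallies, out_dir = out_dir))
}

# Fixed numeric formatting so identical runs are byte-identical.
write_num_csv <- function(d, path) {
  for (cn in names(d)) {
    if (is.numeric(d[[cn]]) && !is.integer(d[[cn]])) {
      d[[cn]] <- formatC(d[[cn]], format = "g", digits = 15)
      d[[cn]][d[[cn]] %in% c("NA", " NA")] <- NA
    }
  }
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}
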