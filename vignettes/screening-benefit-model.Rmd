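---
title: "Modeling the benefit of biennial mammography screening by age cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the benefit of biennial mammography screening by age cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammosim)
set.seed(1)
```

## The question and the model

Whether an organized mammography screening program (MS) should be offered to
an additional two-year age cohort hinges on how much earlier detection is
worth *at that age*: with increasing age a growing share of women destined
to die of breast cancer die of something else first, so the deaths that
screening could prevent are progressively preempted by competing mortality.
`mammosim` quantifies this with an individual-level competing-risks
microsimulation of 21 entry cohorts (ages 40, 42, …, 80), each modeled with
and without biennial screening over 20 years of follow-up.

The model has three ingredients.

**1. Tumor size drives tumor-specific survival.** Tumor diameter at
diagnosis (TD, mm) is the sole prognostic covariate. Fifteen-year
tumor-related survival follows a Gompertz curve,

$$S_{15}(TD) = 100 - 58.4\, e^{-4.46\, e^{-0.071 \cdot TD}} \quad (\%),$$

fitted to cancer-registry survival by 5-mm diameter increments
(`fifteen_year_survival()`, `td_for_survival()`). Screen-detected disease is
smaller: the screening size mix (33.8 / 46.0 / 18.7 % in the classes ≤10,
10–20, >20 mm with mean diameters 7 / 15 / 28 mm) has a renormalized
weighted-mean diameter of 14.7 mm and hence $S_{15}$ = 87.8 %. Allowing for
interval cancers, the screened arm is calibrated to an *effective* 16 mm
(86 %), the unscreened arm to 76 %, i.e. 22.7 mm. The 20-year endpoints used
by the simulator — 81.9 % with and 67.9 % without screening — are carried as
printed calibration constants (`arm_calibration()`); they are deliberately
*not* re-derived from the 15-year values, because no single extrapolation
rule reproduces both (constant cumulative-hazard scaling gives
$0.86^{4/3} = 0.818$ but $0.76^{4/3} = 0.694$).

**2. Two independent clocks per patient.** For every woman diagnosed with
breast cancer, the simulator draws (i) a destined tumor-related death time
from the arm's annual hazard schedule — by default a constant hazard
$h = 1 - s_{20}^{1/20}$ per follow-up year, the minimal assumption
consistent with the calibrated 20-year survival (`build_schedule()`; a
custom 20-vector is accepted for sensitivity analysis) — and (ii) a
tumor-independent death time from the life table's annual probabilities $q$
at her attained integer ages. Both draws are stepwise by year with the date
uniform within the year (`draw_event_year()`). The earliest event wins;
exact ties (probability zero under the continuous within-year date) resolve
to the tumor-independent event.

**3. Metastasis backdating.** A metastasis (MET) is placed a fixed
`met_offset` = 28 months before the would-be tumor death. This splits the
destined tumor deaths (E3) into three patient-relevant endpoints and yields
the taxonomy (`classify_endpoint()`):

* **E1** no event in 20 years; **E2** tumor-independent death only
  (E1 + E2 + E3 = 100 %);
* **E4** tumor death occurs first; **E5** tumor-independent death before
  MET; **E6** tumor-independent death after MET (E3 = E4 + E5 + E6).

Under the unscreened constant-hazard schedule the mean time to destined
tumor death is ≈112 months, so the mean metastasis-free time is ≈84 months
(7 years) and E5 ≈ 3 × E6 at ages where the competing hazard is roughly
flat — both properties are asserted by the test suite.

Lives lost (LL) counts E3; LL~corr~ counts only E4, i.e. deaths actually
realized despite competing mortality. Years of life lost (YLL) attach the
life-table residual expectancy $e$ at the age of the (destined or realized)
tumor death; the arm differences give prevented deaths (PD, PD~corr~),
life-years gained (LY~corr~), and — against 10 screens per woman over 20
years at 88 € each — screens and € per prevented death and per life-year
(`compare_arms()`, `sweep_ages()`, `aggregate_interval()`).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| screening interval | 2 | years | biennial program; 10 screens / 20 y |
| follow-up | 20 | years | fixed design horizon |
| `s20` (ms / no_ms) | 0.819 / 0.679 | fraction | printed 20-year calibration |
| `met_offset` | 28 | months | MET-to-death lag; fixed, config hook |
| `replicates` | 50 | — | averages reported; SE ∝ $1/\sqrt{50}$ |
| `cost_per_mse` | 88 | € | program cost per screen |
| `detection_fraction` | 0.80 | fraction | share found by regular screens; reporting only — its survival effect is already folded into the 16 mm effective-diameter calibration |
| `accrual_mode` | across-rounds | — | see below |

**Accrual mode (open design point).** Two readings of the design are
defensible: diagnoses accrue across the ten screening rounds (each patient
diagnosed at her attained age, followed 20 years from diagnosis), or all
diagnoses occur at the entry age. Cumulative incidence of ≈57 per 1000
women over 20 years implies the former; endpoint distributions close to
1 − s₂₀ per cohort fit either. We default to `"across-rounds"` and expose
`"at-entry"`; the at-entry reading yields lower E2 at mid-life entry ages
because fewer woman-years are spent at high attained ages. Competing
mortality always acts at the attained age.

**Number of diagnoses.** `n_bc` is incidence × woman-years of the 2-year
cohort, with stochastic rounding that preserves the expectation; depletion
of the cohort by death before diagnosis is ignored, consistent with
incidence being applied as a rate to the nominal cohort size.

## The synthetic demography

The real inputs are national statistics (a female life table, breast-cancer
incidence per 100,000 woman-years, and population counts by single year of
age). They are not shipped; `load_demography()` reads them from CSV if the
user exports them. For self-contained runs, generators emulate their
statistical structure with constants calibrated **once** (they are part of
the stated world of the tests and are not tuned):

* `make_life_table()` — Gompertz–Makeham hazard
  $\mu(a) = c + A e^{ba}$ with $c = 2.34\times10^{-3}$,
  $A = 5.76\times10^{-7}$, $b = 0.1388$, fitted so 20-year all-cause
  survival is ≈94 / 75 / 2 % from ages 40 / 60 / 80 — the pattern of a
  current Western European female mortality table. `e` is recomputed from
  `q` by the standard mid-year-death recursion, so the columns are mutually
  consistent; the table closes with `q = 1` at `max_age`.
* `make_incidence()` — logistic rise from 100 per 100k near age 40 to a
  plateau of 310 (inflection 55, width 5), calibrated so entry ages 50–69
  accumulate ≈57 diagnoses per 1000 women over 20 years.
* `make_population()` — ≈27,000 women per single year of age (≈54,000 per
  2-year cohort, the scale of the modeled screening populations), declining
  logistically after ~80.

What the synthetic world does *not* emulate: calendar-time trends, cohort
effects in mortality or incidence, the US-registry incidence alternative,
and the exact age profile of the real supplementary tables. A green test on
synthetic demography therefore establishes the *mechanics and qualitative
age dynamics* (conservation of endpoints, calibration recovery, U-shaped
screens-per-prevented-death, monotone competing-mortality attenuation), not
the published per-cohort values; those require the real tables.

## Numerical choices and degenerate inputs

* Event-year draws use the exact discrete distribution
  $P(\text{year }k) = h_k \prod_{j<k}(1-h_j)$, never an exponential
  approximation; "no event" is a regular outcome (`NA`), with probability
  $\prod_j (1-h_j)$.
* A schedule with no tumor mortality is requested by an explicit flag;
  `s20 = 1` is rejected rather than silently producing empty hazards.
* Ratios against zero prevented deaths (possible at extreme synthetic
  inputs, e.g. zero incidence) are reported as `NA` ("not estimable"),
  never `Inf`.
* Ages beyond the life table's closed end keep `q = 1`; a table that ends
  without closing raises an error instead of extrapolating.
* Age-interval aggregates sum PD, LY and screens across cohorts before
  forming ratios (screen-weighted means), not averages of per-cohort
  ratios.
* Per-(cohort, arm, replicate) seeds are derived from one master seed, so
  any single replicate can be replayed and arms are independently
  reproducible; pipeline CSVs are written with fixed formatting so repeated
  runs are byte-identical.
* E2 saturates at $1 - E3$ in the oldest cohorts, so its increase with age
  is asserted by rank correlation with a Monte-Carlo-sized slack on
  per-step differences rather than strict adjacent inequalities.

## A short run

```{r sweep, eval = FALSE}
demo <- synth_demography()
sw <- sweep_ages(demo, replicates = 50, master_seed = 1)
sw[sw$entry_age %in% c(40, 48, 66, 80),
   c("entry_age", "pd_corr", "mse_per_pd_corr", "mse_per_ly_corr")]
attr(sw, "argmin_mse_per_pd")   # interior optimum of screens per PD
aggregate_interval(sw, 50, 69)  # screen-weighted 50-69 summary
```

`run_pipeline(run_config(), "run/")` executes the same sweep end to end and
writes `tables2_3.csv`, `table4.csv`, the three plot-data CSVs, a config
snapshot and a log with per-replicate seeds.

## Known limitations

Overdiagnosis, false positives, DCIS, quality-of-life effects and
hormone-receptor subgroup dynamics are out of scope by design; one survival
function per arm is assumed for all ages. Tumor deaths after year 20 are not
modeled. The 15→20-year extrapolation is a constant, and how the unscreened
67.9 % was obtained from 76 % is not derivable from the published
description — it is treated as authoritative input, not re-derived. Costs
are raw multiplications (no discounting, no QALYs). Screening sensitivity
and sojourn time are not modeled explicitly; they are absorbed into the
effective-diameter calibration of the screened arm.
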