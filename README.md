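# ahmt — in-instrument preparation of calibration solutions by capillary electrophoresis

Quantitative CE bioanalysis needs a calibration series — typically six or
seven dilutions of a working standard — and preparing it by hand means
pipetting small volumes with all the random error that entails. The
pressure system of a CE instrument can do the job itself: a pressure
pulse of $p$ psi applied for $t$ minutes drives a reproducible volume
through the capillary (Hagen–Poiseuille flow, $Q = \Delta P \pi r^4 / 8
\eta L$), so two consecutive timed transfers — working standard (WS) and
diluent (DBGE) — constitute any intermediate concentration directly in a
collection vial. This package is for analytical chemists who want to
plan, audit or study that automated hydrodynamically mediated technique
(AHMT) without touching an instrument.

At its core are:

* a **dilution scheduler** (`plan_level()`, `plan_series()`) that splits a
  constant pressure–time budget $t_{WS} p_{WS} + t_{DBGE} p_{DBGE} = B$
  between the two transfers in proportion to the target concentration and
  realizes each product on the instrument's quantized pressure/time grids;
* a **flow/volume model** (`poiseuille_flow()`, `delivered_volume()`) and a
  **timed sequence builder** (`build_sequence()`, `reagent_budget()`) giving
  total preparation time and per-liquid consumption;
* a **synthetic electropherogram generator** (`simulate_series()`) with
  known ground truth — Gaussian peaks whose areas scale as
  $f \cdot c \cdot t_m$, shared migration drift, log-normal area noise;
* the associated **statistics**: time-corrected peak areas
  ($\mathrm{TCPA} = A/t_m$), internal-standard ratios, standardized-residual
  outlier screening, $w = 1/x$ weighted calibration (`calibration()`),
  back-calculation, and Deming errors-in-variables regression
  (`deming()`, `compare_modes()`) for comparing automatic against manual
  preparation.

## Worked example

Plan the standard PCR-vial series (stock 100 µg/mL, budget anchored at
10 min / 20 psi per solution):

```r
library(ahmt)
plan <- plan_series(c(6.25, 12.5, 25, 37.5, 50, 75), 100,
                    reference_budget(10, 20), pcr_constraints())
print(plan)
#> AHMT dilution plan: 6 levels, stock 100 ug/mL, budget 400 psi min
#>    level solution t_min p_psi  p_kpa product achieved_conc rel_error undiluted
#> 1   6.25       WS    10   2.5  17.24      25          6.25         0     FALSE
#> 2   6.25     DBGE    15  25.0 172.37     375          6.25         0     FALSE
#> 3  12.50       WS    10   5.0  34.47      50         12.50         0     FALSE
#> 4  12.50     DBGE    14  25.0 172.37     350         12.50         0     FALSE
#> 5  25.00       WS    10  10.0  68.95     100         25.00         0     FALSE
#> 6  25.00     DBGE    10  30.0 206.84     300         25.00         0     FALSE
#> ...
```

Each row is one transfer: the 6.25 µg/mL level takes 10 min at 2.5 psi
of working standard, then 15 min at 25 psi of diluent (the diluent
product, 375 psi·min, cannot be delivered at ≤ 30 psi in the default
10 min, so the scheduler stretches the time minimally while keeping the
product exact). Timing and volumes:

```r
sq <- build_sequence(plan, mode = "R")
sq$total_duration
#> [1] 150.5            # minutes, ~2.5 h for six calibrators
reagent_budget(sq, capillary_geometry(), fluid())$per_vial[[1]]
#> [1] 93.51048         # uL collected per vial, identical across levels
```

Simulate triplicate runs, calibrate, and compare two independently
noised preparations by Deming regression:

```r
plan7 <- plan_series(c(6.25, 12.5, 25, 37.5, 50, 75, 100), 100,
                     reference_budget(10, 20), pcr_constraints())
fits <- calibrate_series(simulate_series(plan7, replicates = 3, seed = 7))
print(fits$prilocaine)
#> Weighted calibration (w = 1/x): y = 0.008311 x +0.0009392, r2 = 0.9998
#>   21 replicate points used, 0 rejected, 7 levels
```

The slope (mL/µg) and intercept are the calibration line of the TCPA
ratio against concentration; back-calculated concentrations come from
`back_calculate(fit, y)`. The whole chain — plan, sequence, simulate
automatic + manual series, calibrate, Deming-compare — runs as
`ahmt_run(ahmt_config())`, or from a shell via
`Rscript inst/cli/ahmt.R run --config cfg.json --out dir/`.

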