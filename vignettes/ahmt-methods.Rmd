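---
title: "Planning and evaluating in-instrument calibration-solution preparation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning and evaluating in-instrument calibration-solution preparation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahmt)
```

## The idea

A capillary electrophoresis (CE) instrument already contains a precise
liquid-handling system: a pressure pump and a narrow fused-silica
capillary. Applying a pressure $\Delta P$ for a time $t$ pushes a
reproducible volume of solution through the capillary, because laminar
flow through a cylinder obeys the Hagen–Poiseuille law

$$ Q = \frac{\Delta P \, \pi r^4}{8 \eta L}, $$

with $r$ the capillary inner radius, $L$ its total length and $\eta$ the
fluid viscosity. Flow is strictly linear in $\Delta P$, so the volume
delivered by a timed transfer depends on pressure and time only through
the product $p \cdot t$. That one fact turns the instrument into a
pipetting robot: a calibration solution of any intermediate concentration
can be constituted inside a collection vial by two consecutive transfers —
working standard (WS, the analyte mixture at $c_{\mathrm{stock}}$) and
diluent (DBGE, a diluted background electrolyte) — with suitably chosen
$(t, p)$ pairs.

## The scheduling rule

All levels of a series share one *pressure–time budget*

$$ t_{WS} p_{WS} + t_{DBGE} p_{DBGE} = B, $$

which (for equal viscosities of WS and DBGE) keeps the collected volume
identical across levels. The budget is anchored at the symmetric 2-fold
dilution, where both transfers use the same reference settings, so
$B = 2\,t_{\mathrm{ref}}\,p_{\mathrm{ref}}$ — 400 psi·min for the
standard PCR-vial series (10 min at 20 psi each) and 40 psi·min for the
low-volume nanoVial series (10 min at 2 psi each). A target
concentration $c$ then fixes the ideal products

$$ P_{WS} = B\,\frac{c}{c_{\mathrm{stock}}}, \qquad P_{DBGE} = B - P_{WS}, $$

and the achieved concentration is
$c_{\mathrm{stock}} P_{WS}/(P_{WS}+P_{DBGE})$ regardless of geometry or
viscosity, which cancel in the ratio.

Real instruments cannot realize arbitrary $(t, p)$: pressures live on a
quantized grid inside a working range, and times are programmed in whole
minutes with a default (the shortest transfer giving repeatable
delivery, 10 min) and a cap (15 min). `plan_level()` resolves each ideal
product in preference order:

1. keep $t$ at the default and round $p$ to the pressure grid (half away
   from zero) if it lands inside the range — the only rule that can
   introduce a (small, reported) dilution error;
2. if the needed pressure is too high, stretch $t$ minimally on the time
   grid until an exactly on-grid pressure preserves the product;
3. if it is too low, pin $p$ at the range minimum and put $t$ on the
   time grid.

Rule 2 is deliberately *minimal-time-first*; no secondary tie-break is
needed on the shipped profiles. The undiluted top calibrator is a
pass-through schedule with no transfers rather than a zero-volume DBGE
step. With the shipped PCR profile (2.5–30 psi, 0.5 psi grid) and
nanoVial profile (from 0.5 psi, 0.1 psi grid, 3.8 psi maximum used) the
planner reproduces the full published schedule table, including the
stretched 15 min and 14 min diluent transfers of the two lowest PCR
levels and the rounded 3.75 → 3.8 psi diluent pressure of the lowest
nanoVial level, whose achieved concentration is then 6.17 rather than
6.25 µg/mL — the one grid-rounding casualty, reported as a −1.2%
relative dilution error.

```{r}
plan <- plan_series(c(6.25, 12.5, 25, 37.5, 50, 75), 100,
                    reference_budget(10, 20), pcr_constraints())
as.data.frame(plan)
```

The nanoVial pressure ceiling (3.8 psi) is the largest pressure the
published nanoVial schedule uses, not an instrument limit; both quanta
(0.5 / 0.1 psi) are inferred from the printed values and are
configurable. Whether the instrument's true pressure resolution is finer
is unknowable from the printed table; any grid consistent with it gives
the same schedules.

## Sequence and volumes

`build_sequence()` expands a plan into the full timed event list: the
initial rinse block (water 1.5, methanol 1.0, air 1.5 min, WS fill
2 min), per-vial WS transfers, a water/DBGE block (3 + 2 min), per-vial
DBGE transfers, a closing rinse block (1.5 min each of water, methanol,
air), and 1 min of 30 psi air bubbling per vial to homogenize. Tip
cleaning between vials is a dip into a water vial with no published
duration; its default is 0 min and it is configurable — the 2.5 h check
below holds with 0. The reverse (R) and forward (F) modes contain
identical events and differ only in which tray is source and which is
collector, so their total durations are equal by construction. For the
six-level PCR series the preparation total is

```{r}
sq <- build_sequence(plan, mode = "R")
sq$total_duration
```

150.5 min ≈ 2.5 h, dominated by the 129 min of transfers — the price of
forcing every transfer through a 50 µm bore. Separation steps (0.5 psi /
6 s injection, 15 kV run) can be emitted as annotation-only events but
are excluded from the preparation total. With the default geometry
(30.5 cm total length — dispensing uses the full length; the 20.5 cm
effective length is detector metadata) and water-like viscosity
0.89 mPa·s (the temperature of the ambient sample tray is not
controlled; viscosity is exposed as configuration), the flow model
predicts 93.5 µL collected per PCR vial and 9.35 µL per nanoVial,
consistent with the reported "about 100 µL" and "down to 10 µL". Those
reported figures were presumably measured, so agreement beyond ~10%
should not be expected; the implied viscosity/temperature is not stated.

## Synthetic electropherograms

`simulate_run()` renders each analyte as a Gaussian peak at its
migration time with true area

$$ A = f \cdot c \cdot t_m, $$

where $f$ is a response factor: a slower analyte resides longer in the
detector window, so its area grows with $t_m$. This is precisely why the
analysis uses *time-corrected peak areas* $\mathrm{TCPA} = A/t_m$ and
the signal $y = \mathrm{TCPA}_{analyte}/\mathrm{TCPA}_{IS}$: a common
velocity change (drift) multiplies all $t_m$ and all $A$ alike and
cancels in the ratio. The generator draws one relative drift per run
(shared by all peaks), multiplicative log-normal area noise (default
CV 2%, sitting under the protocol's CV < 3% repeatability criterion),
and optional additive baseline noise. Migration times 1.6/2.1/2.6 min
and response factors 1.2/1.0/0.55 for procaine (the internal standard),
prilocaine and bupivacaine are fixture choices giving baseline-resolved
peaks — they are not measured values, so parameter-recovery tests
compare against the generator's own ground truth, never against
published calibration slopes. Traces are sampled at 10 Hz over 4 min
(2401 points), where trapezoidal integration of a fully-sampled Gaussian
is accurate to well below 0.1%.

What the generator does *not* emulate: electromigration dispersion and
peak asymmetry, stacking, EOF variation beyond a common drift, detector
saturation, and between-day response changes. Passing tests therefore
demonstrate that the statistical pipeline is implemented correctly and
behaves as designed under idealized CE-like noise — not that any real
instrument meets the published performance.

## Calibration statistics

For each run, `integrate_peaks()` takes a ±0.2 min window around each
nominal migration time, subtracts a baseline estimated as the median of
the outer 5% of window points on each side, and integrates by
trapezoids; an apex below `min_height` above baseline is a named
missing-peak error. The replicate-level signals then pass through, in
order:

1. **outlier screening** — an unweighted line is fitted to all replicate
   points; points with $|e_i|/s > 2$ are discarded, where $s$ is the
   residual standard deviation on $n-2$ degrees of freedom. One pass
   only, no iterative re-rejection. The screening conditions cited in
   the original protocol are not fully specified there, so this package
   fixes the standard choice (threshold 2, configurable) and documents
   it;
2. **averaging** of surviving replicates per level;
3. **weighted least squares** with $w = 1/x$, the standard bioanalytical
   weighting for signals whose noise grows with concentration (the
   weighted fit formulas are implemented directly; $r^2$ uses weighted
   residual and total sums of squares, so $r^2 = 1$ iff all weighted
   residuals vanish).

Back-calculation inverts the line, $\hat x = (y - b)/a$, and accuracy is
reported as $(\hat x - x)/x$. On noise-free synthetic series the
pipeline recovers the generator's slope and intercept to numerical
precision; at 2% area noise with triplicates, mid-range levels
back-calculate within 4% of truth in well over 95% of seeded
repetitions.

## Deming comparison

Comparing automatic against manual preparation regresses back-calculated
concentrations on each other, where *both* axes carry error, so ordinary
least squares would attenuate the slope. `deming()` minimizes

$$ \sum_i \left[ (y_i - \hat y_i)^2 + \delta\,(x_i - \hat x_i)^2 \right],
\qquad \delta = \frac{\sigma^2_y}{\sigma^2_x}, $$

via the closed form
$a = \big[(s_{yy} - \delta s_{xx}) + \sqrt{(s_{yy} - \delta s_{xx})^2 +
4\delta s_{xy}^2}\big] / (2 s_{xy})$, $b = \bar y - a \bar x$. The
orientation is fixed as automatic mode on $y$, manual on $x$, with
$\delta$ the y-to-x error-variance ratio (estimable from mode-wise mean
replicate SDs via `deming_lambda()`); this convention matters because
swapping axes inverts the slope. Limits behave as they must: $\delta \to
\infty$ recovers OLS of $y$ on $x$, $\delta \to 0$ the inverse of OLS of
$x$ on $y$, and $\delta = 1$ is orthogonal (major-axis) regression. A
zero covariance with unequal scaled variances has no defined
orientation and errors out; an isotropic cloud returns slope 1 by
convention.

Standard errors are leave-one-out jackknife estimates. The original
report's analytic SE formula is not stated and its printed SE magnitudes
($10^{-14}$–$10^{-16}$) appear to be a software artifact; they are not
emulated. Published comparison slopes and intercepts derive from
unreleased experimental raw data and are likewise not asserted
numerically anywhere in this package — the synthetic analogue (two
independently noised modes from the same truth) instead checks that the
Deming slope's jackknife CI covers 1.

```{r}
plan7 <- plan_series(c(6.25, 12.5, 25, 37.5, 50, 75, 100), 100,
                     reference_budget(10, 20), pcr_constraints())
set.seed(1)
fa <- calibrate_series(simulate_series(plan7, replicates = 3))$prilocaine
fm <- calibrate_series(simulate_series(plan7, replicates = 3))$prilocaine
compare_modes(back_calculate(fa, fa$data$y),
              back_calculate(fm, fm$data$y), delta = 1)
```

## Numerical choices and degenerate inputs

* Grid membership uses an absolute tolerance of $10^{-9}$; pressures are
  rounded half away from zero (so 3.75 → 3.8, matching the published
  nanoVial row).
* Budget conservation is exact whenever the resolution algorithm avoids
  rule 1 rounding; otherwise the deviation is bounded by one pressure
  quantum times the default time per solution, and the achieved
  concentration is always recomputed from the realized products.
* Mixing uses centered accumulation (deviations from the first
  component), so a species present at equal concentration in all sources
  — the internal standard at 100 µg/mL — comes out *exactly* equal, not
  within a few ulp.
* Infeasible targets (e.g. 0.1 µg/mL under the PCR profile, whose WS
  product would need less than one on-grid minute at minimum pressure)
  raise a scheduling-infeasible error naming the level.
* Problem sizes in the shipped tests: the Monte-Carlo accuracy check
  uses 100 series × 2 analytes (200 calibration curves, triplicate,
  seven levels); oracle-equivalence checks use 100 random datasets per
  closed form with a BFGS + Newton-polish minimizer of the stated
  objective as the independent reference.

## Limitations

The flow model ignores capillary-entrance effects, temperature
gradients, non-Newtonian behavior and siphoning; composition assumes
equal viscosities of WS and DBGE — a real viscosity mismatch would make
the two transfers deliver unequal volumes at equal products, so the
constituted concentration would no longer follow the product ratio. The simulator's noise is idealized as described above.
Scheduling supports exactly two source solutions per level and a single
diluent; multi-step gradients are out of scope.
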