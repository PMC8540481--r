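test_that("reference budgets double the reference product", {
  expect_equal(reference_budget(10, 20), 400)
  expect_equal(reference_budget(10, 2), 40)
  expect_equal(reference_budget(1, 1), 2)
})

test_that("the PCR and nanoVial series reproduce every published schedule cell", {
  pub <- published_schedule()
  got_pcr <- as.data.frame(pcr_plan())[, c("level", "solution", "t_min", "p_psi")]
  expect_equal(got_pcr, pub$pcr, ignore_attr = TRUE)
  got_nano <- as.data.frame(nano_plan())[, c("level", "solution", "t_min", "p_psi")]
  expect_equal(got_nano, pub$nano, ignore_attr = TRUE)
})

test_that("the three resolution rules fire as designed on key levels", {
  # rule 2: DBGE product 375 needs the smallest stretched time with an
  # exact on-grid pressure -> 15 min at 25 psi
  s <- plan_level(6.25, 100, 400, pcr_constraints())
  expect_equal(c(s$dbge_step$duration, s$dbge_step$pressure), c(15, 25))
  expect_equal(c(s$ws_step$duration, s$ws_step$pressure), c(10, 2.5))
  # rule 2 at 12.5: product 350 -> 14 min at 25 psi
  s <- plan_level(12.5, 100, 400, pcr_constraints())
  expect_equal(c(s$dbge_step$duration, s$dbge_step$pressure), c(14, 25))
  # rule 3 (pin at p_min) + rule 1 rounding (3.75 -> 3.8) on the nano level
  s <- plan_level(6.25, 100, 40, nano_constraints())
  expect_equal(c(s$ws_step$duration, s$ws_step$pressure), c(5, 0.5))
  expect_equal(c(s$dbge_step$duration, s$dbge_step$pressure), c(10, 3.8))
  expect_equal(s$achieved_concentration, 2.5 / 40.5 * 100, tolerance = 1e-12)
  expect_equal(s$relative_dilution_error, (2.5 / 40.5 * 100 - 6.25) / 6.25,
               tolerance = 1e-9)
  # symmetric 2-fold level
  s <- plan_level(50, 100, 400, pcr_constraints())
  expect_equal(s$ws_step[c("duration", "pressure")],
               s$dbge_step[c("duration", "pressure")])
})

test_that("an undiluted target becomes a pass-through schedule", {
  s <- plan_level(100, 100, 400, pcr_constraints())
  expect_true(s$undiluted)
  expect_null(s$ws_step)
  expect_equal(s$achieved_concentration, 100)
})

test_that("infeasible and invalid targets raise named errors", {
  expect_error(plan_level(0.1, 100, 400, pcr_constraints()), "infeasible")
  expect_error(plan_level(120, 100, 400, pcr_constraints()), "stock")
  expect_error(plan_level(-5, 100, 400, pcr_constraints()))
  expect_error(plan_series(c(50, 0.1), 100, 400, pcr_constraints()),
               "level 2")
})

test_that("budget is conserved exactly off rule 1, within one quantum step on it", {
  for (plan in list(pcr_plan(), nano_plan())) {
    cn <- attr(plan, "constraints")
    budget <- attr(plan, "budget")
    for (s in plan) {
      dev <- abs(s$ws_step$product + s$dbge_step$product - budget)
      expect_lte(dev, cn$p_quantum * cn$t_default + 1e-9)
    }
  }
  # all PCR levels conserve exactly (all products representable)
  for (s in pcr_plan())
    expect_equal(s$ws_step$product + s$dbge_step$product, 400)
})

test_that("achieved concentration is monotone in the target and deterministic", {
  targets <- sort(c(PCR_TARGETS, 10, 30, 60))
  plan <- plan_series(targets, 100, 400, pcr_constraints())
  ach <- vapply(plan, function(s) s$achieved_concentration, numeric(1))
  expect_true(all(diff(ach) >= 0))
  plan2 <- plan_series(targets, 100, 400, pcr_constraints())
  expect_identical(as.data.frame(plan), as.data.frame(plan2))
})

test_that("time stretching picks the minimal feasible time (exhaustive oracle)", {
  # for every product the scheduler stretches, enumerate the whole
  # (t, p) grid and confirm no smaller feasible t exists
  oracle_min_t <- function(P, cn) {
    t_grid <- seq(cn$t_default + cn$t_quantum, cn$t_max, by = cn$t_quantum)
    p_grid <- seq(cn$p_min, cn$p_max, by = cn$p_quantum)
    feas <- c()
    for (t in t_grid) for (p in p_grid)
      if (abs(t * p - P) < 1e-9) feas <- c(feas, t)
    if (length(feas)) min(feas) else NA_real_
  }
  cn <- pcr_constraints()
  for (target in c(6.25, 12.5)) {
    P <- 400 - 400 * target / 100
    s <- plan_level(target, 100, 400, cn)
    expect_equal(s$dbge_step$duration, oracle_min_t(P, cn))
  }
  # random small grid: every stretched product the scheduler accepts must
  # match the oracle minimum; every infeasible one must have no grid pair
  cn2 <- instrument_constraints(p_min = 1, p_max = 4, p_quantum = 0.5,
                                t_default = 2, t_max = 6, t_quantum = 1)
  set.seed(99)
  feasible <- as.vector(outer(seq(3, 6), seq(1.5, 4, by = 0.5)))
  probes <- c(runif(30, 8.5, 30), sample(feasible[feasible > 8], 10))
  for (P in probes) {
    got <- tryCatch(resolved <- ahmt:::resolve_product(P, cn2),
                    error = function(e) NULL)
    want <- oracle_min_t(P, cn2)
    if (is.null(got)) {
      expect_true(is.na(want), info = sprintf("P = %g", P))
    } else {
      expect_equal(got$duration, want, info = sprintf("P = %g", P))
      expect_equal(got$duration * got$pressure, P, tolerance = 1e-9)
    }
  }
})

test_that("pressure rounding is half away from zero", {
  expect_equal(ahmt:::round_half_away(3.75, 0.1), 3.8)
  expect_equal(ahmt:::round_half_away(2.25, 0.5), 2.5)
  expect_equal(ahmt:::round_half_away(-3.75, 0.1), -3.8)
})
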