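# Shared fixtures: the two published constraint profiles, their targets,
# and the full published schedule table (one row per transfer step).

PCR_TARGETS <- c(6.25, 12.5, 25, 37.5, 50, 75)
STOCK <- 100

pcr_plan <- function(targets = PCR_TARGETS) {
  plan_series(targets, STOCK, reference_budget(10, 20), pcr_constraints())
}

nano_plan <- function(targets = PCR_TARGETS) {
  plan_series(targets, STOCK, reference_budget(10, 2), nano_constraints())
}

# published (t, p) cells for both vial formats
published_schedule <- function() {
  pcr <- data.frame(
    level = rep(PCR_TARGETS, each = 2),
    solution = rep(c("WS", "DBGE"), 6),
    t_min = c(10, 15, 10, 14, 10, 10, 10, 10, 10, 10, 10, 10),
    p_psi = c(2.5, 25, 5, 25, 10, 30, 15, 25, 20, 20, 30, 10))
  nano <- data.frame(
    level = rep(PCR_TARGETS, each = 2),
    solution = rep(c("WS", "DBGE"), 6),
    t_min = c(5, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10),
    p_psi = c(0.5, 3.8, 0.5, 3.5, 1.0, 3.0, 1.5, 2.5, 2.0, 2.0, 3.0, 1.0))
  list(pcr = pcr, nano = nano)
}

# quick noise-free single-replicate series over the 7-level study
noise_free_series <- function(plan = plan_series(c(PCR_TARGETS, 100), STOCK,
                                                 reference_budget(10, 20),
                                                 pcr_constraints())) {
  simulate_series(plan, noise = noise_model(0, 0, 0), replicates = 1, seed = 1)
}

# independent brute-force minimizers of the two regression objectives
# (gradients are straight calculus on the stated objective, not the
# closed forms under test)
wls_oracle <- function(x, y, w, start = c(0.01, 0)) {
  obj <- function(th) sum(w * (y - th[1] * x - th[2])^2)
  gr <- function(th) {
    r <- y - th[1] * x - th[2]
    c(-2 * sum(w * x * r), -2 * sum(w * r))
  }
  th <- optim(start, obj, gr, method = "BFGS",
              control = list(reltol = 1e-16, maxit = 5000))$par
  newton_polish(th, gr)
}

# a few Newton steps on the gradient with a central-difference Jacobian
# pushes the optimizer's answer to machine precision
newton_polish <- function(th, gr, steps = 3, h = 1e-6) {
  for (k in seq_len(steps)) {
    g <- gr(th)
    H <- matrix(0, length(th), length(th))
    for (j in seq_along(th)) {
      e <- numeric(length(th)); e[j] <- h
      H[, j] <- (gr(th + e) - gr(th - e)) / (2 * h)
    }
    th <- th - solve(H, g)
  }
  th
}

deming_oracle <- function(x, y, delta, start = c(1, 0)) {
  obj <- function(th) {
    r <- y - th[1] * x - th[2]
    delta * sum(r^2) / (th[1]^2 + delta)
  }
  gr <- function(th) {
    r <- y - th[1] * x - th[2]
    S <- sum(r^2)
    den <- th[1]^2 + delta
    c(delta * (-2 * sum(x * r) * den - 2 * th[1] * S) / den^2,
      -2 * delta * sum(r) / den)
  }
  th <- optim(start, obj, gr, method = "BFGS",
              control = list(reltol = 1e-16, maxit = 5000))$par
  newton_polish(th, gr)
}

expect_close <- function(x, y, tol = 1e-9) {
  expect_true(all(abs(x - y) <= tol * pmax(abs(y), 1)),
              info = sprintf("max dev %.3g", max(abs(x - y))))
}
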