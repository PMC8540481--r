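test_that("peak integration recovers known Gaussian areas and flags flat traces", {
  an <- list(a1 = analyte_model("a1", 2.0, peak_width_sigma = 0.02))
  time <- seq(0, 4, by = 1 / 600)
  tr <- data.frame(time = time, absorbance = 3.7 * dnorm(time, 2.0, 0.02))
  pk <- integrate_peaks(tr, an)
  expect_equal(pk$area, 3.7, tolerance = 1e-3)
  expect_equal(pk$migration_time, 2.0, tolerance = 1e-3)
  expect_equal(pk$tcpa, pk$area / pk$migration_time)
  flat <- data.frame(time = time, absorbance = rep(0, length(time)))
  expect_error(integrate_peaks(flat, an), "no peak found for a1")
  # window outside trace
  an_far <- list(analyte_model("far", 10))
  expect_error(integrate_peaks(tr, an_far), "outside")
})

test_that("TCPA ratios behave as ratios of area over migration time", {
  peaks <- data.frame(analyte = c("procaine", "x"),
                      migration_time = c(1.0, 2.0),
                      area = c(1.0, 2.0),
                      tcpa = c(1.0, 1.0))
  expect_equal(unname(tcpa_signal(peaks)), 1.0)
  peaks2 <- peaks; peaks2$analyte <- c("is2", "x")
  expect_error(tcpa_signal(peaks2), "internal standard")
  # identical peak to the IS gives y = 1
  same <- data.frame(analyte = c("procaine", "x"),
                     migration_time = c(1.6, 1.6), area = c(2, 2),
                     tcpa = c(1.25, 1.25))
  expect_equal(unname(tcpa_signal(same)), 1)
})

test_that("standardized-residual screening flags only the displaced point", {
  set.seed(21)
  x <- rep(c(6.25, 12.5, 25, 37.5, 50, 75, 100), each = 3)
  y <- 0.02 * x + rnorm(length(x), 0, 0.002)
  y[11] <- 0.02 * x[11] + 0.2   # gross displacement
  flags <- reject_outliers(x, y, threshold = 2)
  expect_true(flags[11])
  expect_equal(sum(flags), 1)
  # collinear points are never flagged; infinite threshold flags nothing
  expect_false(any(reject_outliers(x, 0.02 * x - 0.01, 2)))
  expect_false(any(reject_outliers(x, y, Inf)))
})

test_that("the weighted fit matches an exact line and handles duplicates by averaging", {
  x <- c(6.25, 12.5, 25, 50, 100)
  y <- 0.02 * x - 0.01
  f <- calibration(x, y, screen = FALSE)
  expect_equal(coef(f), c(a = 0.02, b = -0.01), tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  # replicate points are averaged before weighting
  xr <- rep(x, each = 3)
  yr <- 0.02 * xr - 0.01 + rep(c(-1, 0, 1) * 1e-3, times = 5)
  f_rep <- calibration(xr, yr, screen = FALSE)
  f_avg <- calibration(x, vapply(x, function(v) mean(yr[xr == v]), numeric(1)),
                       screen = FALSE)
  expect_equal(coef(f_rep), coef(f_avg), tolerance = 1e-12)
  # refitting the fit's own predictions reproduces (a, b) and r2 = 1
  f2 <- calibration(x, predict(f, x), screen = FALSE)
  expect_equal(coef(f2), coef(f), tolerance = 1e-10)
  expect_equal(f2$r2, 1, tolerance = 1e-12)
})

test_that("weighted fit equals brute-force minimization and lm on 100 random sets", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(4:9, 1)
    x <- sort(runif(n, 1, 100))
    y <- runif(1, 0.005, 0.05) * x + rnorm(n, 0, 0.2 * sqrt(x) * 0.01)
    f <- calibration(x, y, screen = FALSE)
    expect_equal(unname(coef(f)), wls_oracle(x, y, 1 / x), tolerance = 1e-8)
    lmfit <- lm(y ~ x, weights = 1 / x)
    expect_equal(unname(coef(f)), unname(rev(coef(lmfit))), tolerance = 1e-9)
  }
})

test_that("weighted r2 is 1 iff residuals vanish", {
  x <- c(5, 10, 20, 40)
  f_exact <- calibration(x, 0.1 * x + 1, screen = FALSE)
  expect_equal(f_exact$r2, 1, tolerance = 1e-12)
  f_noisy <- calibration(x, 0.1 * x + 1 + c(0.1, -0.1, 0.1, -0.1),
                         screen = FALSE)
  expect_lt(f_noisy$r2, 1 - 1e-6)
  expect_gt(f_noisy$r2, 0)
})

test_that("back-calculation inverts the line and reports relative error", {
  f <- calibration(c(5, 10, 20, 50), 0.02 * c(5, 10, 20, 50) - 0.01,
                   screen = FALSE)
  expect_equal(back_calculate(f, 0.99), 50, tolerance = 1e-10)
  expect_equal(back_calculate(f, predict(f, 17)), 17, tolerance = 1e-10)
  expect_equal(relative_error(f, 50, 0.99), 0, tolerance = 1e-10)
  expect_error(calibration(c(0, 1, 2, 3), 1:4), "positive")
})

test_that("calibration on noise-free simulated series recovers the generator line", {
  fits <- calibrate_series(noise_free_series(), screen = FALSE)
  an <- default_analytes()
  for (nm in c("prilocaine", "bupivacaine")) {
    slope_true <- an[[nm]]$response_factor /
      (an$procaine$response_factor * 100)
    expect_equal(fits[[nm]]$a, slope_true, tolerance = 1e-6)
    expect_equal(fits[[nm]]$b, 0, tolerance = 1e-9)
    expect_equal(fits[[nm]]$r2, 1, tolerance = 1e-10)
  }
})

test_that("calibrating an integrated series matches the generator manifest", {
  plan <- pcr_plan()
  s <- simulate_series(plan, replicates = 1, seed = 42,
                       noise = noise_model(0.02, 0.005, 0))
  an <- default_analytes()
  for (tr in s[1:3]) {
    peaks <- integrate_peaks(tr, an)
    truth <- attr(tr, "truth")
    expect_equal(peaks$area, truth$area, tolerance = 2e-3)
  }
})
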