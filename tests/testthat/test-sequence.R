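test_that("six PCR calibrators take 150.5 min, about 2.5 h, in either mode", {
  plan <- pcr_plan()
  for (mode in c("R", "F")) {
    sq <- build_sequence(plan, mode = mode)
    expect_equal(sq$total_duration, 150.5)
  }
  # composition of the total: fixed protocol blocks + transfer times + mixes
  expect_equal(150.5, 6 + 60 + 5 + 69 + 4.5 + 6)
})

test_that("total duration is additive and mode-invariant", {
  plan <- pcr_plan()
  sq_r <- build_sequence(plan, mode = "R")
  sq_f <- build_sequence(plan, mode = "F")
  expect_equal(sq_r$total_duration, sum(sq_r$events$duration[sq_r$events$counted]))
  expect_equal(sq_r$total_duration, sq_f$total_duration)
  # identical event multiset, only tray annotations differ
  cols <- c("kind", "liquid", "duration", "pressure", "vial")
  expect_identical(sq_r$events[, cols], sq_f$events[, cols])
  expect_false(identical(sq_r$events$source_tray, sq_f$events$source_tray))
})

test_that("a bare protocol reduces the total to transfers plus mixing", {
  s <- plan_level(25, 100, 400, pcr_constraints())
  sq <- build_sequence(list(s), protocol = empty_protocol())
  expect_equal(sq$total_duration,
               s$ws_step$duration + s$dbge_step$duration + 1)
})

test_that("transfer events match schedule steps one-to-one", {
  plan <- pcr_plan()
  sq <- build_sequence(plan)
  tr <- sq$events[sq$events$kind == "transfer", ]
  expect_equal(nrow(tr), 2 * length(plan))
  for (s in plan) {
    v <- sprintf("cal_%g", s$target_concentration)
    ws <- tr[tr$vial == v & tr$liquid == "WS", ]
    expect_equal(c(ws$duration, ws$pressure),
                 c(s$ws_step$duration, s$ws_step$pressure))
    db <- tr[tr$vial == v & tr$liquid == "DBGE", ]
    expect_equal(c(db$duration, db$pressure),
                 c(s$dbge_step$duration, s$dbge_step$pressure))
  }
})

test_that("undiluted levels add no transfer or mix events", {
  plan <- plan_series(c(50, 100), 100, 400, pcr_constraints())
  sq <- build_sequence(plan)
  expect_equal(sum(sq$events$kind == "transfer"), 2)
  expect_equal(sum(sq$events$kind == "mix"), 1)
})

test_that("reagent budget sums the flow model per liquid and per vial", {
  g <- capillary_geometry(); f <- fluid()
  plan <- nano_plan()
  sq <- build_sequence(plan, protocol = empty_protocol())
  b <- reagent_budget(sq, g, f, vial_capacity = 50)
  # WS dispensed through transfers equals the flow model on summed products
  ws_products <- sum(vapply(plan, function(s) s$ws_step$product, numeric(1)))
  expect_equal(unname(b$dispensed["WS"]), product_volume(ws_products, g, f),
               tolerance = 1e-9)
  expect_gt(b$dispensed[["WS"]], 19); expect_lt(b$dispensed[["WS"]], 21)
  # constant budget -> equal collected volume across the PCR series
  bp <- reagent_budget(build_sequence(pcr_plan()), g, f)
  expect_equal(max(bp$per_vial) - min(bp$per_vial), 0, tolerance = 1e-9)
  # no WS events -> no WS budget
  s50 <- plan_level(50, 100, 40, nano_constraints())
  sq50 <- build_sequence(list(s50), protocol = empty_protocol())
  ev <- sq50$events[sq50$events$liquid != "WS" | sq50$events$kind != "transfer", ]
  sq50$events <- ev
  b50 <- reagent_budget(sq50, g, f, vial_capacity = 50)
  expect_false("WS" %in% names(b50$dispensed))
})

test_that("over-capacity collection triggers a warning", {
  plan <- pcr_plan()
  sq <- build_sequence(plan)
  expect_warning(reagent_budget(sq, capillary_geometry(), fluid(),
                                vial_capacity = 50),
                 "capacity")
})

test_that("separation events are annotation-only and uncounted", {
  plan <- pcr_plan()
  sq <- build_sequence(plan, separation = TRUE)
  expect_equal(sq$total_duration, 150.5)
  expect_true(any(sq$events$kind == "separate"))
  expect_false(any(sq$events$counted[sq$events$kind == "separate"]))
})
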