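test_that("variable grid matches the instance dimensions", {
  params <- rt_params(horizon_days = 5, slots_per_day = 4,
                      slot_minutes = 5, frame_lo = 0, frame_hi = 15)
  inst <- rt_instance(
    rt_patients("a", sessions = 1, due_day = 5, duration_slots = 1,
                window_lo = 0, window_hi = 15,
                feasible_linacs = list("L1")),
    rt_linacs("L1", params = params), params)
  m <- build_milp(inst)
  expect_identical(m$n_x, 20L)   # 1 patient x 1 linac x 4 slots x 5 days

  # a 2-slot session can never start on the last slot of the day
  inst2 <- rt_instance(
    rt_patients("a", sessions = 1, due_day = 5, duration_slots = 2,
                window_lo = 0, window_hi = 15,
                feasible_linacs = list("L1")),
    rt_linacs("L1", params = params), params)
  m2 <- build_milp(inst2)
  expect_identical(max(m2$xvars$s), 3L)
  expect_identical(unname(m2$eliminated["eq14"]), 5L)
})

test_that("restricted-frame patients only get in-frame start variables", {
  params <- rt_params()   # frame [60, 570] -> slots 13..115
  inst <- rt_instance(
    rt_patients("a", sessions = 2, due_day = 1, duration_slots = 3,
                window_lo = 90, window_hi = 510, restricted_frame = TRUE,
                feasible_linacs = list("L1")),
    rt_linacs("L1", params = params), params)
  m <- build_milp(inst)
  expect_true(all(m$xvars$s >= 13 & m$xvars$s <= 115))
  expect_gt(m$eliminated["eq15"], 0)
})

test_that("ongoing patients are pinned and fixed assignments respected", {
  params <- rt_params(horizon_days = 2, slots_per_day = 4,
                      slot_minutes = 5, frame_lo = 0, frame_hi = 15)
  lin <- rt_linacs(c("L1", "L2"), params = params)
  pts <- rt_patients(id = c("on", "nw"), sessions = 1, due_day = c(1, 2),
                     duration_slots = 1, window_lo = 0, window_hi = 15,
                     feasible_linacs = list(c("L1", "L2"), c("L1", "L2")),
                     current_linac = c("L2", NA), is_new = c(FALSE, TRUE))
  inst <- rt_instance(pts, lin, params)
  m <- build_milp(inst)
  expect_true(all(m$xvars$k[m$xvars$p == 1] == 2L))
  m2 <- build_milp(inst, fixed_assignment = c(nw = "L1"))
  expect_true(all(m2$xvars$k[m2$xvars$p == 2] == 1L))
  expect_error(build_milp(inst, fixed_assignment = c(on = "L3")))
})

test_that("build refuses invalid instances", {
  inst <- tiny_instance()
  inst$patients$due_day[1] <- 99L
  expect_error(build_milp(inst), "fails validation")
})

test_that("a one-patient all-day-window model solves to zero deviation", {
  inst <- full_window_instance(1, n = 1, k = 1, Tn = 2, S = 6)
  r <- solve_milp(build_milp(inst), time_limit_s = 60)
  expect_identical(r$status, "optimal")
  expect_equal(r$objective, 0)
})

test_that("capacity shortfalls are reported infeasible", {
  params <- rt_params(horizon_days = 1, slots_per_day = 1,
                      slot_minutes = 5, frame_lo = 0, frame_hi = 0)
  inst <- rt_instance(
    rt_patients(c("a", "b"), sessions = 1, due_day = 1,
                duration_slots = 1, window_lo = 0, window_hi = 0,
                feasible_linacs = list("L1", "L1")),
    rt_linacs("L1", params = params), params)
  r <- solve_milp(build_milp(inst), time_limit_s = 60)
  expect_identical(r$status, "infeasible")
  expect_true(is.na(r$objective))
})

test_that("solver objective equals the recomputed deviation sum", {
  for (seed in c(101, 102, 103, 104)) {
    inst <- random_tiny_instance(seed)
    m <- build_milp(inst)
    r <- solve_milp(m, time_limit_s = 60)
    if (r$status != "optimal") next    # infeasible fixtures are fine here
    s <- extract_schedule(m, r)
    expect_equal(r$objective, sum(s$dev_lo + s$dev_hi), tolerance = 1e-6)
    expect_identical(nrow(check_feasibility(s, inst)), 0L)
  }
})

test_that("widening a window never worsens the enumeration optimum", {
  checked <- 0
  for (seed in 201:215) {
    inst <- random_tiny_instance(seed)
    base <- brute_force_optimal(inst)
    if (base$status != "optimal") next
    wide <- inst
    i <- sample(nrow(wide$patients), 1)
    span <- (wide$params$slots_per_day - 1) * wide$params$slot_minutes
    wide$patients$window_lo[i] <- max(0, wide$patients$window_lo[i] - 20)
    wide$patients$window_hi[i] <- min(span,
                                      wide$patients$window_hi[i] + 20)
    after <- brute_force_optimal(wide)
    expect_lte(after$objective, base$objective)
    checked <- checked + 1
  }
  expect_gte(checked, 5)
})

test_that("fractional solutions are refused at extraction", {
  inst <- tiny_instance()
  m <- build_milp(inst)
  r <- solve_milp(m, time_limit_s = 60)
  r$values[seq_len(m$n_x)] <- 0.5
  expect_error(extract_schedule(m, r), "fractional")
  r$status <- "infeasible"
  expect_error(extract_schedule(m, r), "no incumbent")
})

test_that("constraint families are tagged and exportable", {
  inst <- tiny_instance()
  m <- build_milp(inst)
  counts <- constraint_counts(m)
  expect_true(all(c("eq5", "eq6", "eq7", "eq8") %in% names(counts)))
  expect_identical(sum(counts), nrow(m$A))
  lp <- tempfile(fileext = ".lp")
  write_lp(m, lp)
  txt <- readLines(lp)
  expect_identical(txt[1], "Minimize")
  expect_true(any(grepl("^ eq5_", txt)))
  expect_true(any(grepl("Binaries", txt)))
})
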