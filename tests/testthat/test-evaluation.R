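test_that("the 23-of-25 worked example yields a 92% in-window share", {
  ex <- worked_example_schedule(n_outside = 2)
  expect_identical(nrow(check_feasibility(ex$schedule, ex$instance)), 0L)
  m <- compute_metrics(ex$schedule, ex$instance)
  expect_identical(m$sessions_scheduled, 25L)
  expect_identical(m$sessions_outside_window, 2L)
  expect_equal(m$fraction_in_window, 0.92)
})

test_that("per-linac workload and utilization", {
  # 137 15-minute sessions on a 3000-minute machine week: 2055 min, 68.5%
  params <- rt_params(max_new_starts = 30L)
  lin <- rt_linacs("L1", params = params)
  n_full <- 27
  pts <- rt_patients(
    id = sprintf("p%02d", seq_len(n_full + 1)),
    sessions = c(rep(5L, n_full), 2L),
    due_day = 1, duration_slots = 3, window_lo = 0, window_hi = 595,
    feasible_linacs = list("L1"))
  inst <- rt_instance(pts, lin, params)
  sess <- do.call(rbind, lapply(seq_len(n_full + 1), function(i)
    data.frame(patient = pts$id[i], linac = "L1",
               day = seq_len(pts$sessions[i]),
               start_slot = 1L + (i - 1L) * 3L)))
  sch <- rt_schedule(sess, inst)
  expect_identical(nrow(check_feasibility(sch, inst)), 0L)
  m <- compute_metrics(sch, inst)
  expect_identical(m$sessions_scheduled, 137L)
  expect_equal(m$per_linac$workload_min, 2055)
  expect_equal(m$per_linac$utilization, 0.685)
  expect_equal(m$cumulative_deviation, 0)
})

test_that("the checker catches hand-made violations", {
  params <- rt_params(horizon_days = 2, slots_per_day = 6,
                      slot_minutes = 5, frame_lo = 5, frame_hi = 20)
  lin <- rt_linacs(c("L1", "L2"), params = params)
  pts <- rt_patients(
    id = c("a", "b", "fr"), sessions = c(2, 1, 1), due_day = c(1, 1, 2),
    duration_slots = c(2, 2, 1), window_lo = 0, window_hi = 25,
    feasible_linacs = list(c("L1", "L2"), "L1", c("L1", "L2")),
    restricted_frame = c(FALSE, FALSE, TRUE))
  inst <- rt_instance(pts, lin, params)

  # overlapping 2-slot sessions on the same linac-day
  v <- check_feasibility(
    data.frame(patient = c("a", "b", "fr"), linac = "L1",
               day = c(1, 1, 2), start_slot = c(1, 2, 2)), inst)
  expect_true(any(v$family == "eq8/eq13"))

  # sessions of one patient split over two machines
  v <- check_feasibility(
    data.frame(patient = c("a", "a", "b", "fr"),
               linac = c("L1", "L2", "L1", "L1"),
               day = c(1, 2, 1, 2), start_slot = c(1, 1, 4, 2)), inst)
  expect_true(any(v$family == "continuity"))

  # missing patient, late start, frame breach, off-pattern days
  v <- check_feasibility(
    data.frame(patient = c("a", "a", "fr"), linac = "L1",
               day = c(1, 2, 2), start_slot = c(3, 6, 1)), inst)
  expect_true(any(v$family == "eq7" & v$patient == "b"))
  expect_true(any(v$family == "eq14"))     # 2-slot start on slot 6 of 6
  expect_true(any(v$family == "eq15" & v$patient == "fr"))

  # due-day and spacing-pattern breaches
  pts2 <- rt_patients("sp", sessions = 2, due_day = 1,
                      duration_slots = 1, spacing_days = 2,
                      window_lo = 0, window_hi = 25,
                      feasible_linacs = list("L1"))
  params3 <- rt_params(horizon_days = 3, slots_per_day = 6,
                       slot_minutes = 5, frame_lo = 0, frame_hi = 25)
  inst2 <- rt_instance(pts2, rt_linacs("L1", params = params3), params3)
  v <- check_feasibility(data.frame(patient = "sp", linac = "L1",
                                    day = c(1, 2), start_slot = c(1, 1)),
                         inst2)
  expect_true(any(v$family == "eq2-4"))    # day 2 breaks the 2-day spacing
  v <- check_feasibility(data.frame(patient = "sp", linac = "L1",
                                    day = c(2, 3), start_slot = 1), inst2)
  expect_true(any(v$family == "eq7"))      # started after the due day

  # new-start cap
  params4 <- rt_params(horizon_days = 1, slots_per_day = 10,
                       slot_minutes = 5, max_new_starts = 1,
                       frame_lo = 0, frame_hi = 45)
  pts4 <- rt_patients(c("n1", "n2"), sessions = 1, due_day = 1,
                      duration_slots = 1, window_lo = 0, window_hi = 45,
                      feasible_linacs = list("L1", "L1"))
  inst4 <- rt_instance(pts4, rt_linacs("L1", params = params4), params4)
  v <- check_feasibility(data.frame(patient = c("n1", "n2"), linac = "L1",
                                    day = 1, start_slot = c(1, 5)), inst4)
  expect_true(any(v$family == "eq12"))

  # blocked starting slot
  lin5 <- rt_linacs("L1", unavailable = list(cbind(day = 1, slot = 5)),
                    params = params4)
  inst5 <- rt_instance(pts4[1, ], lin5, params4)
  v <- check_feasibility(data.frame(patient = "n1", linac = "L1",
                                    day = 1, start_slot = 5), inst5)
  expect_true(any(v$family == "eq8"))
})

test_that("empty schedules give zero counts and undefined fractions", {
  inst <- tiny_instance()
  sch <- rt_schedule(data.frame(patient = character(),
                                linac = character(), day = integer(),
                                start_slot = integer()), inst)
  m <- compute_metrics(sch, inst)
  expect_identical(m$sessions_scheduled, 0L)
  expect_true(is.na(m$fraction_outside))
  expect_true(is.na(m$avg_deviation_outside))
  expect_equal(m$cumulative_deviation, 0)
})

test_that("average deviation is over out-of-window sessions only", {
  ex <- worked_example_schedule(n_outside = 2)
  m <- compute_metrics(ex$schedule, ex$instance)
  dev <- ex$schedule$dev_lo + ex$schedule$dev_hi
  expect_equal(m$avg_deviation_outside, sum(dev) / 2)
  expect_equal(m$cumulative_deviation, sum(dev))
})
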