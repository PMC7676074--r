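test_that("default configuration encodes the documented center profile", {
  cfg <- default_nki_config()
  expect_equal(vapply(cfg$window_menu, `[[`, numeric(1), "prob"),
               c(0.25, 0.50, 0.25))
  expect_equal(cfg$window_menu[[1]]$window, c(0, 90))
  expect_equal(cfg$window_menu[[2]]$window, c(90, 510))
  expect_equal(cfg$window_menu[[3]]$window, c(510, 600))
  expect_identical(cfg$params$max_new_starts, 6L)
  expect_identical(cfg$params$slots_per_day, 120L)
  expect_identical(cfg$params$horizon_days, 5L)
  expect_equal(cfg$params$slot_minutes, 5)
  expect_equal(c(cfg$params$frame_lo, cfg$params$frame_hi), c(60, 570))
  expect_equal(cfg$new_patient_fraction, 0.35)

  plans <- cfg$care_plans
  probs <- vapply(plans, `[[`, numeric(1), "prob")
  labels <- vapply(plans, `[[`, character(1), "label")
  expect_equal(sum(probs), 1)
  expect_equal(probs[labels == "Bone metastasis"], 0.233)
  expect_equal(probs[labels == "Breast"], 0.165)
  # aggregate marginals hold exactly by construction
  expect_equal(sum(probs * vapply(plans, function(p) p$dur_probs[2], 1)),
               0.605)
  expect_equal(sum(probs * vapply(plans, function(p) sum(p$dur_probs[3:5]),
                                  1)), 0.199)
  expect_equal(sum(probs * vapply(plans, `[[`, numeric(1), "urgency")),
               0.34)
  expect_equal(sum(probs[vapply(plans, function(p) p$spacing >= 2L,
                                logical(1))]), 0.06)
  expect_equal(sum(probs[vapply(plans, `[[`, logical(1), "frame")]), 0.21)
  expect_true(all(unlist(lapply(plans, `[[`, "sess_values")) >= 1))
  expect_true(all(unlist(lapply(plans, `[[`, "sess_values")) <= 35))
})

test_that("generation is deterministic under the seed", {
  a <- generate_instance(default_nki_config(n_patients = 30, n_linacs = 2,
                                            seed = 7))
  b <- generate_instance(default_nki_config(n_patients = 30, n_linacs = 2,
                                            seed = 7))
  expect_identical(a$patients, b$patients)
  expect_identical(a$linacs$id, b$linacs$id)
  c <- generate_instance(default_nki_config(n_patients = 30, n_linacs = 2,
                                            seed = 8))
  expect_false(identical(a$patients, c$patients))
  # the caller's RNG stream is left untouched
  set.seed(99); before <- runif(1)
  set.seed(99); generate_instance(default_nki_config(n_patients = 5,
                                                     n_linacs = 1,
                                                     seed = 3))
  expect_identical(runif(1), before)
})

test_that("sampled patients respect the documented supports", {
  set.seed(31)
  pts <- sample_patients(default_nki_config(), 400,
                         linac_ids = paste0("L", 1:8))
  expect_true(all((pts$duration_slots * 5) %in% c(10, 15, 20, 25, 30)))
  expect_true(all(pts$sessions >= 1 & pts$sessions <= 35))
  expect_true(all(pts$due_day %in% 1:5))
  expect_true(all(pts$due_day[!pts$is_new] == 1L))
  expect_true(all(!is.na(pts$current_linac[!pts$is_new])))
  expect_true(all(is.na(pts$current_linac[pts$is_new])))
  expect_true(all(pts$spacing_days %in% c(1L, 2L)))
  expect_true(all(pts$window_lo >= 0 & pts$window_hi <= 600))
})

test_that("large-sample shares recover the configured probabilities", {
  set.seed(12)
  n <- 10000
  pts <- sample_patients(default_nki_config(), n)
  tol3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(pts$duration_slots * 5 == 15) - 0.605), tol3(0.605))
  expect_lt(abs(mean(pts$urgent) - 0.34), tol3(0.34))
  expect_lt(abs(mean(pts$is_new) - 0.35), tol3(0.35))
  expect_lt(abs(mean(pts$window_lo == 0 & pts$window_hi == 90) - 0.25),
            tol3(0.25))
  expect_lt(abs(mean(pts$window_lo == 90 & pts$window_hi == 510) - 0.50),
            tol3(0.50))
  expect_lt(abs(mean(pts$spacing_days == 2) - 0.06), tol3(0.06))
  expect_lt(abs(mean(pts$restricted_frame) - 0.21), tol3(0.21))
  expect_lt(abs(mean(pts$duration_slots * 5 >= 20) - 0.199), tol3(0.199))
})

test_that("generator rejects degenerate configurations", {
  expect_error(generate_instance(default_nki_config(), n_linacs = 0),
               "at least one linac")
  expect_error(generate_instance(default_nki_config(), n_patients = 0),
               "at least one patient")
})
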