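# Synthetic instance generator calibrated to the empirical patient mix of
# a large Dutch radiotherapy center (approx. 4700 new treatment courses per
# year, 8 linacs, 260 patients per week). Only the two largest care plans
# are publicly documented with their exact shares; the remaining mass is
# absorbed by a small set of synthetic plans whose distributions are
# completed *in code* so that the documented aggregate marginals hold
# exactly: 60.5% of patients with 15-min sessions, 19.9% with sessions of
# 20 min or more, 34% urgent, 6% with a >= 2-day spacing scheme and 21%
# restricted to the staff-presence frame.

#' Default generator configuration (NKI-calibrated)
#'
#' Encodes the documented weekly patient mix of a large Dutch center:
#' session counts between 1 and 35 depending on care plan, durations of
#' 10--30 minutes in 5-minute multiples with 60.5% at 15 minutes and 19.9%
#' at 20 minutes or more, a 34%/66% urgent/regular split, 35% new patients,
#' due dates 1--5, a 25/50/25 split over the morning ([0, 90] min), midday
#' ([90, 510] min) and late ([510, 600] min) preference windows, 6% of
#' patients on spaced (every-other-day) schemes and 21% of patients bound
#' to the 08h30--17h00 staff-presence frame. The day grid is 120 slots of
#' 5 minutes (07h30--17h30) over a 5-day horizon with at most 6 new
#' patients starting per linac per day.
#'
#' The care-plan table names the two largest documented plans ("Bone
#' metastasis", 23.3%; "Breast", 16.5%) plus synthetic plans; the residual
#' plan's duration and urgency probabilities are solved from the aggregate
#' marginals above, so the configuration reproduces them exactly by
#' construction.
#'
#' @param n_patients Number of patients to generate (default 260, the
#'   center's weekly load).
#' @param n_linacs Number of linacs (default 8).
#' @param seed Integer seed making generation deterministic.
#' @return An object of class `rt_gen_config`.
#' @export
default_nki_config <- function(n_patients = 260L, n_linacs = 8L,
                               seed = 1L) {
  plan <- function(label, prob, urgency, dur_probs, sess_values,
                   sess_probs, spacing = 1L, frame = FALSE) {
    stopifnot(abs(sum(dur_probs) - 1) < 1e-9,
              abs(sum(sess_probs) - 1) < 1e-9,
              length(sess_values) == length(sess_probs),
              all(sess_values >= 1), all(sess_values <= 35))
    list(label = label, prob = prob, urgency = urgency,
         dur_probs = dur_probs, sess_values = as.integer(sess_values),
         sess_probs = sess_probs,
         due_probs = rep(0.2, 5),   # uniform on 1..5 (calibration knob)
         spacing = as.integer(spacing), frame = frame)
  }
  # durations are over c(10, 15, 20, 25, 30) minutes
  plans <- list(
    plan("Bone metastasis", 0.233, 0.60, c(.50, .45, .05, 0, 0),
         c(1, 2, 3, 5, 10), c(.25, .15, .25, .20, .15)),
    plan("Breast", 0.165, 0.08, c(.05, .85, .10, 0, 0),
         c(5, 15, 16, 21), c(.20, .35, .30, .15)),
    plan("Prostate", 0.100, 0.05, c(0, .80, .15, .05, 0),
         c(20, 35), c(.50, .50)),
    plan("Lung", 0.090, 0.35, c(.05, .70, .20, .05, 0),
         c(5, 15, 24, 30, 33), c(.15, .25, .25, .20, .15)),
    plan("Head and neck", 0.080, 0.20, c(0, .40, .30, .20, .10),
         c(30, 33, 35), c(.30, .40, .30), frame = TRUE),
    plan("Stereotactic/hypofractionated", 0.060, 0.25,
         c(0, .20, .30, .30, .20), c(3, 5, 8), c(.40, .40, .20),
         spacing = 2L, frame = TRUE),
    plan("CNS (specialist present)", 0.070, 0.30,
         c(0, .60, .25, .10, .05), c(10, 13, 30), c(.40, .30, .30),
         frame = TRUE)
  )
  named_mass <- sum(vapply(plans, `[[`, numeric(1), "prob"))
  resid <- 1 - named_mass
  # complete the residual plan so the aggregate marginals hold exactly
  p15 <- sum(vapply(plans, function(p) p$prob * p$dur_probs[2], numeric(1)))
  pge20 <- sum(vapply(plans, function(p) p$prob * sum(p$dur_probs[3:5]),
                      numeric(1)))
  purg <- sum(vapply(plans, function(p) p$prob * p$urgency, numeric(1)))
  d15 <- (0.605 - p15) / resid
  dge20 <- (0.199 - pge20) / resid
  d10 <- 1 - d15 - dge20
  urg <- (0.340 - purg) / resid
  stopifnot(d15 >= 0, d15 <= 1, dge20 >= 0, d10 >= 0, urg >= 0, urg <= 1)
  plans <- c(plans, list(
    plan("Other (residual mix)", resid, urg, c(d10, d15, dge20, 0, 0),
         c(1:8, 12, 25), c(rep(.09, 8), .16, .12))))
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_linacs = as.integer(n_linacs),
    seed = as.integer(seed),
    care_plans = plans,
    durations_min = c(10, 15, 20, 25, 30),
    new_patient_fraction = 0.35,
    monday_start_fraction = 0,      # share not documented; off by default
    window_menu = list(
      list(window = c(0, 90), prob = 0.25),
      list(window = c(90, 510), prob = 0.50),
      list(window = c(510, 600), prob = 0.25)
    ),
    satellite_ids = c("L7", "L8"),
    params = rt_params()
  )
  probs <- vapply(cfg$care_plans, `[[`, numeric(1), "prob")
  wprobs <- vapply(cfg$window_menu, `[[`, numeric(1), "prob")
  stopifnot(abs(sum(probs) - 1) < 1e-9, abs(sum(wprobs) - 1) < 1e-9)
  class(cfg) <- "rt_gen_config"
  cfg
}

#' @export
print.rt_gen_config <- function(x, ...) {
  cat(sprintf("Generator config: %d patients, %d linacs, seed %d\n",
              x$n_patients, x$n_linacs, x$seed))
  cat(sprintf("  %d care plans; new fraction %.2f; windows %s\n",
              length(x$care_plans), x$new_patient_fraction,
              paste(sprintf("[%g,%g]@%.3g",
                            vapply(x$window_menu, function(w) w$window[1], 1),
                            vapply(x$window_menu, function(w) w$window[2], 1),
                            vapply(x$window_menu, `[[`, numeric(1), "prob")),
                    collapse = " ")))
  invisible(x)
}

# draw one index from a probability vector using the current RNG stream
draw <- function(probs) sample.int(length(probs), 1L, prob = probs)

#' Sample a single patient
#'
#' Draws a care plan, then the plan-conditional session count, duration,
#' urgency and due date, the preference window from the window menu, and
#' the new/ongoing status. Ongoing patients get due day 1, a uniformly
#' drawn current linac and a uniformly drawn number of remaining sessions
#' (mid-treatment progress is unobserved). Uses and advances the current
#' RNG stream; seed management belongs to [generate_instance()].
#'
#' @param config An `rt_gen_config`.
#' @param id Patient identifier.
#' @param linac_ids Character vector of linac ids in the instance.
#' @return A one-row patient data frame (see [rt_patients()]).
#' @export
sample_patient <- function(config, id = "p1",
                           linac_ids = paste0("L", seq_len(config$n_linacs))) {
  pl <- config$care_plans[[draw(vapply(config$care_plans, `[[`, numeric(1),
                                       "prob"))]]
  w <- config$window_menu[[draw(vapply(config$window_menu, `[[`, numeric(1),
                                       "prob"))]]$window
  total_sessions <- pl$sess_values[draw(pl$sess_probs)]
  dur_min <- config$durations_min[draw(pl$dur_probs)]
  urgent <- stats::runif(1) < pl$urgency
  is_new <- stats::runif(1) < config$new_patient_fraction
  monday <- is_new && stats::runif(1) < config$monday_start_fraction
  feas <- linac_ids                      # no pre-allocation by default
  if (is_new) {
    sessions <- total_sessions
    due <- if (monday) 1L else draw(pl$due_probs)
    cur <- NA_character_
  } else {
    sessions <- sample.int(total_sessions, 1L)
    due <- 1L
    cur <- feas[sample.int(length(feas), 1L)]
  }
  rt_patients(
    id = id, care_plan = pl$label, is_new = is_new,
    must_start_monday = monday, restricted_frame = pl$frame,
    sessions = sessions, due_day = due,
    duration_slots = as.integer(dur_min / config$params$slot_minutes),
    spacing_days = pl$spacing,
    window_lo = w[1], window_hi = w[2],
    feasible_linacs = list(feas), current_linac = cur, urgent = urgent
  )
}

#' Sample a table of patients
#'
#' @param config An `rt_gen_config`.
#' @param n Number of patients.
#' @param linac_ids Linac ids available in the instance.
#' @return A patient data frame with `n` rows.
#' @export
sample_patients <- function(config, n = config$n_patients,
                            linac_ids = paste0("L",
                                               seq_len(config$n_linacs))) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- sample_patient(config, id = sprintf("p%03d", i),
                                linac_ids = linac_ids)
  }
  do.call(rbind, rows)
}

#' Generate a complete synthetic scheduling instance
#'
#' Deterministic under `config$seed` (restores the caller's RNG state on
#' exit). The generated instance always passes [validate_instance()].
#'
#' @param config An `rt_gen_config`, e.g. [default_nki_config()].
#' @param n_patients,n_linacs,seed Optional overrides of the config fields.
#' @return An `rt_instance`.
#' @export
generate_instance <- function(config = default_nki_config(),
                              n_patients = config$n_patients,
                              n_linacs = config$n_linacs,
                              seed = config$seed) {
  if (n_linacs < 1L) stop("config error: at least one linac is required")
  if (n_patients < 1L) stop("config error: at least one patient is required")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  ids <- paste0("L", seq_len(n_linacs))
  linacs <- rt_linacs(
    id = ids,
    location = ifelse(ids %in% config$satellite_ids, "satellite", "main"),
    params = config$params
  )
  patients <- sample_patients(config, n_patients, linac_ids = ids)
  rt_instance(patients, linacs, config$params)
}
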