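# Core domain types: planner parameters, linacs, patients, instances,
# schedules, and the slot/minute coordinate arithmetic shared by every
# other module. Days and slots are 1-based throughout; a slot s of width
# l minutes starts l*(s-1) minutes after the day opens.

#' Planner parameters
#'
#' Global parameters of the weekly planning problem: the horizon length in
#' days, the slot grid of each linac-day, the cap on patients starting
#' treatment on the same linac and day, and the restricted staff-presence
#' frame applied to patients that require a specialist in the department.
#'
#' @param horizon_days Number of days in the planning horizon (default 5,
#'   one labour week Monday--Friday).
#' @param slots_per_day Number of bookable slots per linac per day
#'   (default 120, a 07h30--17h30 opening at 5-minute resolution).
#' @param slot_minutes Slot width in minutes (default 5).
#' @param max_new_starts Maximum number of new patients allowed to start
#'   treatment on the same linac and the same day (default 6).
#' @param frame_lo,frame_hi Restricted time frame, in minutes from day
#'   opening, bounding the starting time of sessions of restricted-frame
#'   patients (defaults 60 and 570, i.e. 08h30--17h00).
#' @return An object of class `rt_params`.
#' @export
rt_params <- function(horizon_days = 5L, slots_per_day = 120L,
                      slot_minutes = 5, max_new_starts = 6L,
                      frame_lo = 60, frame_hi = 570) {
  p <- list(
    horizon_days = as.integer(horizon_days),
    slots_per_day = as.integer(slots_per_day),
    slot_minutes = as.numeric(slot_minutes),
    max_new_starts = as.integer(max_new_starts),
    frame_lo = as.numeric(frame_lo),
    frame_hi = as.numeric(frame_hi)
  )
  stopifnot(p$horizon_days >= 1L, p$slots_per_day >= 1L, p$slot_minutes > 0)
  if (p$frame_lo > p$frame_hi) stop("frame_lo must not exceed frame_hi")
  class(p) <- "rt_params"
  p
}

#' @export
print.rt_params <- function(x, ...) {
  cat(sprintf(
    "Planner parameters: %d days x %d slots of %g min (%g min/day),\n",
    x$horizon_days, x$slots_per_day, x$slot_minutes,
    x$slots_per_day * x$slot_minutes))
  cat(sprintf("  new-start cap %d/linac/day, restricted frame [%g, %g] min\n",
              x$max_new_starts, x$frame_lo, x$frame_hi))
  invisible(x)
}

#' Linac table constructor
#'
#' @param id Character vector of linac identifiers.
#' @param location `"main"` or `"satellite"` per linac. Satellite machines
#'   may never share a cluster with main-site machines.
#' @param capacity_min Weekly capacity in minutes; defaults to the full
#'   open slot grid minus any blocked slots.
#' @param unavailable List (one element per linac) of two-column matrices
#'   `(day, slot)` of blocked slots; `NULL` elements mean fully available.
#' @param params An [rt_params()] object used for the capacity default.
#' @return A data frame with one row per linac and a list-column
#'   `unavailable`.
#' @export
rt_linacs <- function(id, location = "main", capacity_min = NULL,
                      unavailable = NULL, params = rt_params()) {
  id <- as.character(id)
  n <- length(id)
  if (anyDuplicated(id)) stop("duplicated linac ids")
  location <- rep_len(as.character(location), n)
  if (!all(location %in% c("main", "satellite")))
    stop("location must be 'main' or 'satellite'")
  if (is.null(unavailable)) unavailable <- vector("list", n)
  blocked <- vapply(unavailable, function(u) if (is.null(u)) 0L else nrow(u),
                    integer(1))
  if (is.null(capacity_min)) {
    capacity_min <- params$slot_minutes *
      (params$slots_per_day * params$horizon_days - blocked)
  }
  out <- data.frame(id = id, location = location,
                    capacity_min = as.numeric(capacity_min),
                    stringsAsFactors = FALSE)
  out$unavailable <- unavailable
  out
}

#' Patient table constructor
#'
#' One row per patient. `feasible_linacs` is a list-column of character
#' vectors (the pre-allocation set of machines able to treat the patient);
#' `current_linac` is `NA` for new patients and the machine an ongoing
#' patient is already being treated on otherwise.
#'
#' @param id Character vector of patient identifiers.
#' @param sessions Remaining sessions to deliver (>= 1).
#' @param due_day Latest day of the horizon by which treatment must have
#'   (re)started.
#' @param duration_slots Session duration in slots.
#' @param spacing_days Days between consecutive sessions (1 = daily).
#' @param window_lo,window_hi Preferred time window for session starts, in
#'   minutes from day opening.
#' @param feasible_linacs List of character vectors of feasible linac ids.
#' @param current_linac Current machine for ongoing patients, `NA` for new.
#' @param is_new Logical; `TRUE` for patients who have not started
#'   treatment.
#' @param care_plan Care plan label.
#' @param must_start_monday Logical; patients whose treatment must start on
#'   day 1 (combined-modality coordination).
#' @param restricted_frame Logical; patients whose session starts must fall
#'   inside the staff-presence frame.
#' @param urgent Optional logical urgency flag (used by the generator and
#'   reporting; it does not enter the optimization model).
#' @return A data frame with one row per patient.
#' @export
rt_patients <- function(id, sessions, due_day, duration_slots,
                        spacing_days = 1L, window_lo = 0,
                        window_hi = Inf, feasible_linacs,
                        current_linac = NA_character_, is_new = TRUE,
                        care_plan = "unspecified",
                        must_start_monday = FALSE,
                        restricted_frame = FALSE, urgent = NA) {
  id <- as.character(id)
  n <- length(id)
  if (anyDuplicated(id)) stop("duplicated patient ids")
  if (!is.list(feasible_linacs)) feasible_linacs <- list(feasible_linacs)
  feasible_linacs <- rep_len(feasible_linacs, n)
  out <- data.frame(
    id = id,
    care_plan = rep_len(as.character(care_plan), n),
    is_new = rep_len(as.logical(is_new), n),
    must_start_monday = rep_len(as.logical(must_start_monday), n),
    restricted_frame = rep_len(as.logical(restricted_frame), n),
    sessions = rep_len(as.integer(sessions), n),
    due_day = rep_len(as.integer(due_day), n),
    duration_slots = rep_len(as.integer(duration_slots), n),
    spacing_days = rep_len(as.integer(spacing_days), n),
    window_lo = rep_len(as.numeric(window_lo), n),
    window_hi = rep_len(as.numeric(window_hi), n),
    current_linac = rep_len(as.character(current_linac), n),
    urgent = rep_len(as.logical(urgent), n),
    stringsAsFactors = FALSE
  )
  out$feasible_linacs <- lapply(feasible_linacs, as.character)
  out
}

#' Scheduling instance
#'
#' Bundles the patient table, the linac table and the planner parameters.
#'
#' @param patients A patient table from [rt_patients()] or the generator.
#' @param linacs A linac table from [rt_linacs()].
#' @param params An [rt_params()] object.
#' @param validate Run [validate_instance()] and fail on violations.
#' @return An object of class `rt_instance`.
#' @export
rt_instance <- function(patients, linacs, params = rt_params(),
                        validate = TRUE) {
  inst <- structure(list(patients = patients, linacs = linacs,
                         params = params),
                    class = "rt_instance")
  if (validate) {
    v <- validate_instance(inst)
    if (nrow(v) > 0)
      stop("invalid instance: ", paste(v$message, collapse = "; "))
  }
  inst
}

#' @export
print.rt_instance <- function(x, ...) {
  cat(sprintf("Radiotherapy scheduling instance: %d patients, %d linacs\n",
              nrow(x$patients), nrow(x$linacs)))
  cat(sprintf("  %d new / %d ongoing; %d restricted-frame; %d spaced (b >= 2)\n",
              sum(x$patients$is_new), sum(!x$patients$is_new),
              sum(x$patients$restricted_frame),
              sum(x$patients$spacing_days >= 2L)))
  print(x$params)
  invisible(x)
}

#' Minutes from day opening at which a slot starts
#'
#' @param s Slot index (1-based).
#' @param l Slot width in minutes.
#' @return `l * (s - 1)` minutes.
#' @export
slot_start_minutes <- function(s, l) {
  if (any(s < 1)) stop("invalid slot: slot indices are 1-based")
  l * (s - 1)
}

#' Convert a minute frame to the range of admissible starting slots
#'
#' Returns the smallest slot starting at or after `frame_lo` and the
#' largest slot starting at or before `frame_hi`. A session only has to
#' *start* inside the frame; it may run past `frame_hi`.
#'
#' @param frame_lo,frame_hi Frame bounds in minutes from day opening.
#' @param l Slot width in minutes.
#' @param n_slots Number of slots per day.
#' @return Integer vector `c(first, last)` of admissible starting slots.
#' @export
frame_to_slot_range <- function(frame_lo, frame_hi, l, n_slots) {
  stopifnot(frame_lo >= 0, frame_lo <= frame_hi,
            frame_hi <= n_slots * l)
  first <- as.integer(ceiling(frame_lo / l)) + 1L
  last <- as.integer(floor(frame_hi / l)) + 1L
  first <- max(first, 1L)
  last <- min(last, as.integer(n_slots))
  if (first > last)
    stop("infeasible frame: no slot starts inside [",
         frame_lo, ", ", frame_hi, "] minutes")
  c(first, last)
}

#' Days on which sessions must take place given a first-session day
#'
#' Starting on day `start_day`, sessions recur every `spacing` days until
#' either all `n_sessions` sessions are delivered or the horizon ends.
#'
#' @param start_day Day of the first session (1-based).
#' @param spacing Days between consecutive sessions (`b_i`).
#' @param n_sessions Remaining sessions (`I_i`).
#' @param horizon Days in the horizon.
#' @return Increasing integer vector of session days.
#' @export
required_session_days <- function(start_day, spacing, n_sessions, horizon) {
  stopifnot(start_day >= 1, start_day <= horizon, spacing >= 1,
            n_sessions >= 1)
  start_day <- as.integer(start_day)
  spacing <- as.integer(spacing)
  last <- min(as.integer(horizon),
              start_day + spacing * (as.integer(n_sessions) - 1L))
  seq.int(start_day, last, by = spacing)
}

#' Validate a scheduling instance
#'
#' Pure structural check; violations are returned as data, never raised.
#'
#' @param instance An `rt_instance` (or a bare list with the same fields).
#' @return A data frame with columns `entity`, `id` and `message`; zero
#'   rows for a well-formed instance.
#' @export
validate_instance <- function(instance) {
  pts <- instance$patients
  lns <- instance$linacs
  par <- instance$params
  bad <- list()
  note <- function(entity, id, message) {
    bad[[length(bad) + 1L]] <<- data.frame(
      entity = entity, id = id, message = paste0(id, ": ", message),
      stringsAsFactors = FALSE)
  }
  day_span <- par$slots_per_day * par$slot_minutes
  if (par$frame_lo > par$frame_hi)
    note("params", "params", "frame_lo exceeds frame_hi")
  for (j in seq_len(nrow(lns))) {
    u <- lns$unavailable[[j]]
    if (!is.null(u) && nrow(u) > 0) {
      if (any(u[, 1] < 1 | u[, 1] > par$horizon_days) ||
          any(u[, 2] < 1 | u[, 2] > par$slots_per_day))
        note("linac", lns$id[j], "blocked slot outside the day/slot grid")
    }
  }
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    kset <- p$feasible_linacs[[1]]
    if (length(kset) == 0)
      note("patient", p$id, "empty feasible linac set")
    if (!all(kset %in% lns$id))
      note("patient", p$id, "feasible linac set names an unknown linac")
    if (p$sessions < 1L)
      note("patient", p$id, "non-positive remaining session count")
    if (p$duration_slots < 1L)
      note("patient", p$id, "non-positive session duration")
    if (p$duration_slots > par$slots_per_day)
      note("patient", p$id, "session longer than the day")
    if (p$spacing_days < 1L)
      note("patient", p$id, "non-positive session spacing")
    if (p$due_day < 1L || p$due_day > par$horizon_days)
      note("patient", p$id, "due date beyond horizon")
    if (p$must_start_monday && p$due_day != 1L)
      note("patient", p$id, "Monday starter must have due date 1")
    if (is.na(p$window_lo) || is.na(p$window_hi) ||
        p$window_lo < 0 || p$window_lo > p$window_hi)
      note("patient", p$id, "ill-formed preference window")
    else if (p$window_hi > day_span && is.finite(p$window_hi))
      note("patient", p$id, "preference window exceeds the day span")
    if (!p$is_new) {
      if (is.na(p$current_linac))
        note("patient", p$id, "ongoing patient without a current linac")
      else {
        if (!(p$current_linac %in% lns$id))
          note("patient", p$id, "current linac is not a known linac")
        if (!(p$current_linac %in% kset))
          note("patient", p$id,
               "current linac is outside the feasible linac set")
      }
      if (p$due_day != 1L)
        note("patient", p$id, "ongoing patient must have due date 1")
    }
    if (p$restricted_frame) {
      ok <- tryCatch({
        frame_to_slot_range(par$frame_lo, par$frame_hi, par$slot_minutes,
                            par$slots_per_day)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) note("patient", p$id, "restricted frame admits no start slot")
    }
  }
  if (length(bad) == 0)
    data.frame(entity = character(), id = character(),
               message = character(), stringsAsFactors = FALSE)
  else do.call(rbind, bad)
}

#' Smallest window deviation of a session start
#'
#' For a session starting at slot `s`, the smallest nonnegative deviations
#' from the preferred window: `dev_lo = max(0, t_min - l(s-1))` and
#' `dev_hi = max(0, l(s-1) - t_max)`.
#'
#' @param s Starting slot (vectorized).
#' @param l Slot width in minutes.
#' @param window Numeric `c(t_min, t_max)` in minutes.
#' @return A list with numeric components `dev_lo` and `dev_hi`.
#' @export
min_deviation <- function(s, l, window) {
  m <- slot_start_minutes(s, l)
  list(dev_lo = pmax(0, window[1] - m), dev_hi = pmax(0, m - window[2]))
}

#' Construct a schedule object
#'
#' @param sessions Data frame with columns `patient`, `linac`, `day`,
#'   `start_slot` (one row per booked session).
#' @param instance The instance the sessions refer to; used to attach
#'   start minutes, durations and window deviations.
#' @return An object of class `rt_schedule`: the session table augmented
#'   with `start_min`, `duration_min`, `dev_lo`, `dev_hi` and `in_window`.
#' @export
rt_schedule <- function(sessions, instance) {
  stopifnot(all(c("patient", "linac", "day", "start_slot") %in%
                  names(sessions)))
  l <- instance$params$slot_minutes
  sessions <- data.frame(patient = as.character(sessions$patient),
                         linac = as.character(sessions$linac),
                         day = as.integer(sessions$day),
                         start_slot = as.integer(sessions$start_slot),
                         stringsAsFactors = FALSE)
  idx <- match(sessions$patient, instance$patients$id)
  if (anyNA(idx)) stop("schedule references unknown patients")
  if (!all(sessions$linac %in% instance$linacs$id))
    stop("schedule references unknown linacs")
  sessions <- sessions[order(sessions$linac, sessions$day,
                             sessions$start_slot), , drop = FALSE]
  idx <- match(sessions$patient, instance$patients$id)
  sessions$start_min <- slot_start_minutes(sessions$start_slot, l)
  sessions$duration_min <- instance$patients$duration_slots[idx] * l
  sessions$dev_lo <- pmax(0, instance$patients$window_lo[idx] -
                            sessions$start_min)
  sessions$dev_hi <- pmax(0, sessions$start_min -
                            instance$patients$window_hi[idx])
  sessions$in_window <- sessions$dev_lo == 0 & sessions$dev_hi == 0
  rownames(sessions) <- NULL
  structure(sessions, class = c("rt_schedule", "data.frame"))
}

#' @export
print.rt_schedule <- function(x, ...) {
  cat(sprintf("Schedule: %d sessions, %d outside window, %g min deviation\n",
              nrow(x), sum(!x$in_window), sum(x$dev_lo + x$dev_hi)))
  NextMethod()
}
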