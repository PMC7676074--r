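# Solver-independent schedule validation and quality metrics. The checker
# re-states every scheduling rule declaratively on the booked sessions, so
# a schedule extracted from the optimizer can be certified without
# trusting the optimizer; the metrics mirror the operational reporting of
# a planning department (share of sessions inside the requested window,
# deviation minutes, per-machine workload and utilization).

violation <- function(family, patient, linac, day, message) {
  data.frame(family = family, patient = patient, linac = linac,
             day = if (is.null(day)) NA_integer_ else as.integer(day),
             message = message, stringsAsFactors = FALSE)
}

#' Check a schedule against every scheduling rule
#'
#' Verifies, without any solver: at most one session per patient per day;
#' at most the remaining session count per patient; treatment started by
#' the due day; all of a patient's sessions on one (feasible) machine,
#' ongoing patients on their current machine; session days following the
#' every-`b_i`-days pattern from the first session until the session count
#' or horizon is exhausted; starts on available slots that leave room for
#' the session before day end; no overlapping slot footprints on a
#' machine-day; the new-start cap per machine-day; and the restricted
#' staff-presence frame for flagged patients.
#'
#' @param schedule An `rt_schedule` (or a data frame with columns
#'   `patient`, `linac`, `day`, `start_slot`).
#' @param instance The `rt_instance` the schedule refers to.
#' @return A data frame of violations (zero rows when feasible) with
#'   columns `family`, `patient`, `linac`, `day`, `message`.
#' @export
check_feasibility <- function(schedule, instance) {
  pts <- instance$patients
  lns <- instance$linacs
  par <- instance$params
  S <- par$slots_per_day
  out <- list()
  add <- function(...) out[[length(out) + 1L]] <<- violation(...)
  sch <- as.data.frame(schedule)

  bad_pat <- !(sch$patient %in% pts$id)
  for (r in which(bad_pat))
    add("reference", sch$patient[r], sch$linac[r], sch$day[r],
        "unknown patient")
  bad_lin <- !(sch$linac %in% lns$id)
  for (r in which(bad_lin))
    add("reference", sch$patient[r], sch$linac[r], sch$day[r],
        "unknown linac")
  sch <- sch[!bad_pat & !bad_lin, , drop = FALSE]

  frame_range <- tryCatch(
    frame_to_slot_range(par$frame_lo, par$frame_hi, par$slot_minutes, S),
    error = function(e) c(1L, 0L))

  for (i in seq_len(nrow(pts))) {
    id <- pts$id[i]
    rows <- sch[sch$patient == id, , drop = FALSE]
    if (nrow(rows) == 0) {
      add("eq7", id, NA_character_, NULL,
          "patient never starts treatment")
      next
    }
    if (anyDuplicated(rows$day))
      add("eq5", id, NA_character_, NULL,
          "more than one session on the same day")
    if (nrow(rows) > pts$sessions[i])
      add("eq6", id, NA_character_, NULL,
          sprintf("%d sessions booked, %d remaining", nrow(rows),
                  pts$sessions[i]))
    ks <- unique(rows$linac)
    if (length(ks) > 1)
      add("continuity", id, paste(ks, collapse = ","), NULL,
          "sessions split over several linacs")
    if (!all(ks %in% pts$feasible_linacs[[i]]))
      add("eq9", id, ks[1], NULL, "session on an infeasible linac")
    if (!pts$is_new[i] && !all(ks == pts$current_linac[i]))
      add("eq9", id, ks[1], NULL,
          "ongoing patient moved off the current linac")
    first <- min(rows$day)
    if (first > pts$due_day[i])
      add("eq7", id, NA_character_, first,
          "first session after the due day")
    expected <- required_session_days(first, pts$spacing_days[i],
                                      pts$sessions[i], par$horizon_days)
    if (!setequal(rows$day, expected))
      add("eq2-4", id, NA_character_, first,
          sprintf("session days {%s} do not follow the required pattern {%s}",
                  paste(sort(rows$day), collapse = ","),
                  paste(expected, collapse = ",")))
    if (any(rows$start_slot < 1 |
            rows$start_slot > S - pts$duration_slots[i] + 1L))
      add("eq14", id, NA_character_, NULL,
          "session does not fit before the end of the day")
    if (pts$restricted_frame[i] &&
        any(rows$start_slot < frame_range[1] |
            rows$start_slot > frame_range[2]))
      add("eq15", id, NA_character_, NULL,
          "start outside the restricted staff-presence frame")
  }

  # start-slot availability (blocked slots)
  for (j in seq_len(nrow(lns))) {
    u <- lns$unavailable[[j]]
    if (is.null(u) || nrow(u) == 0) next
    rows <- sch[sch$linac == lns$id[j], , drop = FALSE]
    hit <- paste(rows$day, rows$start_slot) %in% paste(u[, 1], u[, 2])
    for (r in which(hit))
      add("eq8", rows$patient[r], lns$id[j], rows$day[r],
          "session starts on a blocked slot")
  }

  # footprint overlap per linac-day
  dur <- pts$duration_slots[match(sch$patient, pts$id)]
  for (g in split(seq_len(nrow(sch)),
                  paste(sch$linac, sch$day))) {
    if (length(g) < 2) next
    o <- g[order(sch$start_slot[g])]
    ends <- sch$start_slot[o] + dur[o] - 1L
    clash <- which(sch$start_slot[o][-1] <= ends[-length(o)])
    for (ci in clash)
      add("eq8/eq13", paste(sch$patient[o][ci], sch$patient[o][ci + 1],
                            sep = "+"),
          sch$linac[o][1], sch$day[o][1],
          "overlapping session footprints")
  }

  # new-start cap per linac-day
  firsts <- do.call(rbind, lapply(split(sch, sch$patient), function(rr)
    rr[which.min(rr$day), c("patient", "linac", "day")]))
  if (!is.null(firsts) && nrow(firsts) > 0) {
    firsts <- firsts[pts$is_new[match(firsts$patient, pts$id)], ,
                     drop = FALSE]
    if (nrow(firsts) > 0) {
      counts <- table(paste(firsts$linac, firsts$day))
      over <- counts[counts > par$max_new_starts]
      for (nm in names(over)) {
        parts <- strsplit(nm, " ")[[1]]
        add("eq12", NA_character_, parts[1], as.integer(parts[2]),
            sprintf("%d new patients start (cap %d)", over[[nm]],
                    par$max_new_starts))
      }
    }
  }

  if (length(out) == 0)
    violation(character(0), character(0), character(0), integer(0),
              character(0))
  else do.call(rbind, out)
}

#' Schedule quality metrics
#'
#' Per-session window deviations (a session is in-window iff its start
#' incurs zero deviation; starts exactly on a window bound count as
#' inside), their total in minutes (the optimization objective), the mean
#' deviation over out-of-window sessions only, and per-linac workload,
#' utilization and patient counts.
#'
#' @param schedule An `rt_schedule`.
#' @param instance The corresponding `rt_instance`.
#' @return An object of class `rt_metrics`.
#' @export
compute_metrics <- function(schedule, instance) {
  sch <- if (inherits(schedule, "rt_schedule")) schedule
  else rt_schedule(as.data.frame(schedule), instance)
  n <- nrow(sch)
  dev <- sch$dev_lo + sch$dev_hi
  outside <- sum(!sch$in_window)
  lin <- data.frame(
    linac = instance$linacs$id,
    workload_min = vapply(instance$linacs$id, function(k)
      sum(sch$duration_min[sch$linac == k]), numeric(1)),
    capacity_min = instance$linacs$capacity_min,
    n_patients = vapply(instance$linacs$id, function(k)
      length(unique(sch$patient[sch$linac == k])), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  lin$utilization <- lin$workload_min / lin$capacity_min
  structure(list(
    sessions_scheduled = n,
    sessions_outside_window = outside,
    fraction_outside = if (n > 0) outside / n else NA_real_,
    fraction_in_window = if (n > 0) 1 - outside / n else NA_real_,
    cumulative_deviation = sum(dev),
    avg_deviation_outside = if (outside > 0)
      sum(dev) / outside else NA_real_,
    per_linac = lin
  ), class = "rt_metrics")
}

#' @export
print.rt_metrics <- function(x, ...) {
  cat(sprintf("Sessions scheduled: %d; outside window: %d (%s)\n",
              x$sessions_scheduled, x$sessions_outside_window,
              if (is.na(x$fraction_outside)) "n/a"
              else sprintf("%.1f%%", 100 * x$fraction_outside)))
  cat(sprintf("Cumulative deviation: %g min; mean over outside: %s\n",
              x$cumulative_deviation,
              if (is.na(x$avg_deviation_outside)) "n/a"
              else sprintf("%.1f min", x$avg_deviation_outside)))
  print(x$per_linac)
  invisible(x)
}
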