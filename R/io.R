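# Readers/writers for the persisted formats. Instances, pre-assignments,
# schedules and reports travel as JSON (schedules and patient tables also
# as CSV); generator configuration overrides come from YAML. All
# coordinates are 1-based days/slots; windows and frames are minutes from
# day opening.

stop_parse <- function(path, field, why) {
  stop(sprintf("parse error in %s: field '%s' %s", path, field, why),
       call. = FALSE)
}

need <- function(x, field, path) {
  if (is.null(x[[field]])) stop_parse(path, field, "is missing")
  x[[field]]
}

#' Write an instance to JSON
#'
#' @param instance An `rt_instance`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instance <- function(instance, path) {
  par <- instance$params
  lns <- instance$linacs
  pts <- instance$patients
  obj <- list(
    params = list(
      horizon_days = par$horizon_days,
      slots_per_day = par$slots_per_day,
      slot_minutes = par$slot_minutes,
      max_new_starts = par$max_new_starts,
      frame = c(par$frame_lo, par$frame_hi)
    ),
    linacs = lapply(seq_len(nrow(lns)), function(j) {
      u <- lns$unavailable[[j]]
      list(id = lns$id[j], location = lns$location[j],
           capacity_min = lns$capacity_min[j],
           unavailable = if (is.null(u) || nrow(u) == 0) list()
           else lapply(seq_len(nrow(u)), function(r)
             c(u[r, 1], u[r, 2])))
    }),
    patients = lapply(seq_len(nrow(pts)), function(i) {
      p <- list(id = pts$id[i], care_plan = pts$care_plan[i],
                new = pts$is_new[i],
                monday_start = pts$must_start_monday[i],
                restricted_frame = pts$restricted_frame[i],
                sessions = pts$sessions[i], due_day = pts$due_day[i],
                duration_slots = pts$duration_slots[i],
                spacing_days = pts$spacing_days[i],
                window = c(pts$window_lo[i], pts$window_hi[i]),
                feasible_linacs = pts$feasible_linacs[[i]])
      if (!is.na(pts$current_linac[i]))
        p$current_linac <- pts$current_linac[i]
      if (!is.na(pts$urgent[i])) p$urgent <- pts$urgent[i]
      p
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an instance from JSON
#'
#' @param path Path to an instance JSON file.
#' @param validate Fail on validation violations (default `TRUE`).
#' @return An `rt_instance`.
#' @export
read_instance <- function(path, validate = TRUE) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  pj <- need(obj, "params", path)
  params <- rt_params(
    horizon_days = need(pj, "horizon_days", path),
    slots_per_day = need(pj, "slots_per_day", path),
    slot_minutes = need(pj, "slot_minutes", path),
    max_new_starts = need(pj, "max_new_starts", path),
    frame_lo = need(pj, "frame", path)[[1]],
    frame_hi = need(pj, "frame", path)[[2]]
  )
  lj <- need(obj, "linacs", path)
  linacs <- rt_linacs(
    id = vapply(lj, function(x) need(x, "id", path), character(1)),
    location = vapply(lj, function(x) need(x, "location", path),
                      character(1)),
    capacity_min = vapply(lj, function(x) need(x, "capacity_min", path),
                          numeric(1)),
    unavailable = lapply(lj, function(x) {
      u <- x$unavailable
      if (is.null(u) || length(u) == 0) return(NULL)
      m <- do.call(rbind, lapply(u, function(r)
        c(as.integer(r[[1]]), as.integer(r[[2]]))))
      colnames(m) <- c("day", "slot")
      m
    }),
    params = params
  )
  pj <- need(obj, "patients", path)
  if (length(pj) == 0) stop_parse(path, "patients", "is empty")
  pts <- do.call(rbind, lapply(pj, function(x) {
    w <- need(x, "window", path)
    rt_patients(
      id = need(x, "id", path),
      care_plan = if (is.null(x$care_plan)) "unspecified" else x$care_plan,
      is_new = need(x, "new", path),
      must_start_monday = isTRUE(x$monday_start),
      restricted_frame = isTRUE(x$restricted_frame),
      sessions = need(x, "sessions", path),
      due_day = need(x, "due_day", path),
      duration_slots = need(x, "duration_slots", path),
      spacing_days = need(x, "spacing_days", path),
      window_lo = w[[1]], window_hi = w[[2]],
      feasible_linacs = list(unlist(need(x, "feasible_linacs", path))),
      current_linac = if (is.null(x$current_linac)) NA_character_
      else x$current_linac,
      urgent = if (is.null(x$urgent)) NA else x$urgent
    )
  }))
  inst <- rt_instance(pts, linacs, params, validate = FALSE)
  if (validate) {
    v <- validate_instance(inst)
    if (nrow(v) > 0)
      stop(sprintf("invalid instance in %s: %s", path,
                   paste(v$message, collapse = "; ")), call. = FALSE)
  }
  inst
}

#' Write / read a pre-assignment
#'
#' @param preassignment An `rt_preassignment`.
#' @param path JSON file path.
#' @return `path` (write) or an `rt_preassignment` (read).
#' @export
write_preassignment <- function(preassignment, path) {
  jsonlite::write_json(list(assignment = as.list(preassignment$assignment),
                            workloads = as.list(preassignment$workloads)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_preassignment
#' @export
read_preassignment <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(assignment = unlist(need(obj, "assignment", path)),
                 workloads = unlist(need(obj, "workloads", path))),
            class = "rt_preassignment")
}

#' Write a schedule to JSON or CSV
#'
#' One row/record per session: patient, linac, day, start slot, start
#' minutes, duration minutes and the in-window flag. The format follows
#' the file extension.
#'
#' @param schedule An `rt_schedule`.
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  df <- as.data.frame(schedule)[, c("patient", "linac", "day",
                                    "start_slot", "start_min",
                                    "duration_min", "in_window")]
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(list(sessions = df), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a schedule written by [write_schedule()]
#'
#' @param path `.json` or `.csv` schedule file.
#' @param instance The `rt_instance` the sessions refer to; unknown
#'   patient or linac ids raise a parse error.
#' @return An `rt_schedule`.
#' @export
read_schedule <- function(path, instance) {
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    utils::read.csv(path, stringsAsFactors = FALSE)
  else jsonlite::read_json(path, simplifyVector = TRUE)$sessions
  if (is.null(df) || nrow(df) == 0)
    return(rt_schedule(data.frame(patient = character(),
                                  linac = character(), day = integer(),
                                  start_slot = integer()), instance))
  for (f in c("patient", "linac", "day", "start_slot"))
    if (is.null(df[[f]])) stop_parse(path, f, "is missing")
  if (!all(df$linac %in% instance$linacs$id))
    stop_parse(path, "linac", paste0(
      "names unknown linac(s): ",
      paste(setdiff(df$linac, instance$linacs$id), collapse = ", ")))
  if (!all(df$patient %in% instance$patients$id))
    stop_parse(path, "patient", paste0(
      "names unknown patient(s): ",
      paste(setdiff(df$patient, instance$patients$id), collapse = ", ")))
  rt_schedule(df[, c("patient", "linac", "day", "start_slot")], instance)
}

#' Write a metrics report to JSON or CSV
#'
#' JSON carries an `aggregate` section and a `per_linac` section; CSV
#' holds the per-linac table only.
#'
#' @param metrics An `rt_metrics` object.
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(metrics, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(metrics$per_linac, path, row.names = FALSE)
  } else {
    jsonlite::write_json(list(
      aggregate = metrics[c("sessions_scheduled",
                            "sessions_outside_window",
                            "fraction_outside", "fraction_in_window",
                            "cumulative_deviation",
                            "avg_deviation_outside")],
      per_linac = metrics$per_linac
    ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Read a cluster specification from YAML
#'
#' The file holds a list of lists of linac ids.
#'
#' @param path YAML file path.
#' @return A cluster spec (list of character vectors).
#' @export
read_cluster_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  if (!is.list(spec) || length(spec) == 0)
    stop_parse(path, "clusters", "must be a non-empty list of lists")
  lapply(spec, function(cl) as.character(unlist(cl)))
}

#' Load a generator configuration, optionally overridden from YAML
#'
#' Starts from [default_nki_config()] and overwrites any field named in
#' the YAML file (`n_patients`, `n_linacs`, `seed`,
#' `new_patient_fraction`, `monday_start_fraction`, `satellite_ids`,
#' `window_menu` as a list of `{window: [lo, hi], prob: p}`, and planner
#' `params` fields).
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return An `rt_gen_config`.
#' @export
read_gen_config <- function(path = NULL) {
  cfg <- default_nki_config()
  if (is.null(path)) return(cfg)
  ov <- yaml::read_yaml(path)
  for (f in c("n_patients", "n_linacs", "seed", "new_patient_fraction",
              "monday_start_fraction", "satellite_ids"))
    if (!is.null(ov[[f]])) cfg[[f]] <- ov[[f]]
  cfg$n_patients <- as.integer(cfg$n_patients)
  cfg$n_linacs <- as.integer(cfg$n_linacs)
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(ov$window_menu)) {
    cfg$window_menu <- lapply(ov$window_menu, function(w)
      list(window = as.numeric(unlist(w$window)),
           prob = as.numeric(w$prob)))
    probs <- vapply(cfg$window_menu, `[[`, numeric(1), "prob")
    if (abs(sum(probs) - 1) > 1e-9)
      stop_parse(path, "window_menu", "probabilities must sum to 1")
  }
  if (!is.null(ov$params)) {
    pf <- ov$params
    cfg$params <- rt_params(
      horizon_days = pf$horizon_days %||% cfg$params$horizon_days,
      slots_per_day = pf$slots_per_day %||% cfg$params$slots_per_day,
      slot_minutes = pf$slot_minutes %||% cfg$params$slot_minutes,
      max_new_starts = pf$max_new_starts %||% cfg$params$max_new_starts,
      frame_lo = pf$frame_lo %||% cfg$params$frame_lo,
      frame_hi = pf$frame_hi %||% cfg$params$frame_hi)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
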