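# Orchestration: optional greedy pre-assignment, cluster partitioning,
# sequential per-cluster solves and schedule merging; plus an exhaustive
# enumeration oracle used to certify optimality on tiny instances.

#' Solve an instance end to end
#'
#' With `clusters = "none"` the whole instance is solved as a single MILP
#' (no pre-assignment; ongoing patients are still pinned to their current
#' machine). Otherwise new patients are first pre-assigned with the greedy
#' workload-balancing heuristic, the instance is partitioned into the
#' given linac clusters, and each cluster is built and solved in sequence
#' under an even split of the total time budget. A cluster that times out
#' or is infeasible is reported as such without aborting the remaining
#' clusters.
#'
#' @param instance An `rt_instance`.
#' @param clusters `"none"`, or a list of character vectors of linac ids
#'   partitioning the machines (never mixing main and satellite sites).
#' @param time_limit_s Total solver time budget in seconds, split evenly
#'   across clusters (default 28800).
#' @param gap_tol Relative MIP gap tolerance per solve.
#' @param preassign_order Passed to [preassign()].
#' @return An `rt_run_result`: merged `schedule`, per-cluster `reports`,
#'   `log` (one row per cluster: status, objective, gap, seconds),
#'   aggregate `objective`, overall `status`, `metrics` and the
#'   `preassignment` used (if any).
#' @export
solve_sequential <- function(instance, clusters = "none",
                             time_limit_s = 28800, gap_tol = 1e-4,
                             preassign_order = "input") {
  pre <- NULL
  if (identical(clusters, "none")) {
    subs <- list(instance)
    labels <- "all"
  } else {
    pre <- preassign(instance, order = preassign_order)
    subs <- partition_clusters(instance, pre, clusters)
    labels <- vapply(clusters, paste, character(1), collapse = "+")
  }
  per_cluster_limit <- time_limit_s / length(subs)
  reports <- vector("list", length(subs))
  schedules <- vector("list", length(subs))
  log <- data.frame(cluster = labels, n_patients = NA_integer_,
                    status = NA_character_, objective = NA_real_,
                    gap = NA_real_, seconds = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(subs)) {
    sub <- subs[[j]]
    log$n_patients[j] <- nrow(sub$patients)
    if (nrow(sub$patients) == 0) {
      reports[[j]] <- structure(list(status = "optimal", objective = 0,
                                     gap = 0, wall_time = 0,
                                     values = NULL),
                                class = "rt_solve_report")
      log$status[j] <- "optimal"; log$objective[j] <- 0
      log$gap[j] <- 0; log$seconds[j] <- 0
      next
    }
    rep_j <- tryCatch({
      model <- build_milp(sub)
      r <- solve_milp(model, time_limit_s = per_cluster_limit,
                      gap_tol = gap_tol)
      if (r$status %in% c("optimal", "feasible"))
        schedules[[j]] <- extract_schedule(model, r)
      r
    }, rt_solver_unavailable = function(e) stop(e),
    error = function(e) {
      structure(list(status = "error", objective = NA_real_,
                     gap = NA_real_, wall_time = NA_real_, values = NULL,
                     message = conditionMessage(e)),
                class = "rt_solve_report")
    })
    reports[[j]] <- rep_j
    log$status[j] <- rep_j$status
    log$objective[j] <- rep_j$objective
    log$gap[j] <- rep_j$gap
    log$seconds[j] <- rep_j$wall_time
  }
  solved <- !vapply(schedules, is.null, logical(1))
  merged <- if (any(solved))
    rt_schedule(do.call(rbind, lapply(schedules[solved],
                                      as.data.frame))[,
      c("patient", "linac", "day", "start_slot")], instance)
  else rt_schedule(data.frame(patient = character(), linac = character(),
                              day = integer(), start_slot = integer()),
                   instance)
  statuses <- vapply(reports, `[[`, character(1), "status")
  status <- if (all(statuses == "optimal")) "optimal"
  else if (all(statuses %in% c("infeasible", "error"))) "infeasible"
  else "feasible"
  structure(list(
    schedule = merged,
    reports = reports,
    log = log,
    objective = if (any(solved)) sum(log$objective[solved]) else NA_real_,
    status = status,
    metrics = compute_metrics(merged, instance),
    preassignment = pre
  ), class = "rt_run_result")
}

#' @export
print.rt_run_result <- function(x, ...) {
  cat(sprintf("Run result: status %s, objective %g min\n",
              x$status, x$objective))
  print(x$log)
  invisible(x)
}

# all admissible single-session start options of one patient, as a list of
# (linac index, start day, per-day start slots, deviation cost) candidates
oracle_too_large <- function(n, guard) {
  stop(structure(class = c("rt_oracle_too_large", "error", "condition"),
                 list(message = sprintf(
                   "oracle search space too large (%g > %g)", n, guard),
                   call = sys.call(-1))))
}

patient_options <- function(instance, i, frame_range, blocked,
                            guard = 1e7) {
  pts <- instance$patients
  par <- instance$params
  S <- par$slots_per_day
  l <- par$slot_minutes
  kset <- if (pts$is_new[i]) pts$feasible_linacs[[i]] else
    pts$current_linac[i]
  kidx <- match(kset, instance$linacs$id)
  p_i <- pts$duration_slots[i]
  s_all <- seq_len(S - p_i + 1L)
  if (pts$restricted_frame[i])
    s_all <- s_all[s_all >= frame_range[1] & s_all <= frame_range[2]]
  opts <- list()
  for (k in kidx) {
    for (t0 in seq_len(pts$due_day[i])) {
      days <- required_session_days(t0, pts$spacing_days[i],
                                    pts$sessions[i], par$horizon_days)
      per_day <- lapply(days, function(t) {
        s <- s_all
        if (length(blocked) > 0)
          s <- s[!(((t - 1L) * S + (s - 1L)) * nrow(instance$linacs) + k)
                 %in% blocked]
        s
      })
      if (any(lengths(per_day) == 0)) next
      if (length(opts) + prod(lengths(per_day)) > guard)
        oracle_too_large(length(opts) + prod(lengths(per_day)), guard)
      combos <- expand.grid(per_day, KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(combos))) {
        slots <- as.integer(combos[r, ])
        dev <- min_deviation(slots, l,
                             c(pts$window_lo[i], pts$window_hi[i]))
        opts[[length(opts) + 1L]] <- list(
          k = k, days = days, slots = slots,
          cost = sum(dev$dev_lo + dev$dev_hi))
      }
    }
  }
  opts
}

#' Exhaustive-enumeration optimum for tiny instances
#'
#' Independent oracle: enumerates every assignment of linac, start day and
#' per-day starting slots that satisfies the scheduling rules (continuity,
#' spacing, due dates, availability, non-overlap, new-start caps,
#' restricted frames) and returns the minimum total window deviation.
#' Refuses search spaces above `guard` candidate schedules.
#'
#' @param instance An `rt_instance` (intended scale: <= 3 patients, <= 2
#'   linacs, <= 2 days, <= 8 slots).
#' @param guard Maximum admissible product of per-patient option counts.
#' @return A list with `status` (`"optimal"` or `"infeasible"`) and
#'   `objective` (minutes; `NA` when infeasible).
#' @export
brute_force_optimal <- function(instance, guard = 1e7) {
  par <- instance$params
  S <- par$slots_per_day
  Tn <- par$horizon_days
  Kn <- nrow(instance$linacs)
  frame_range <- tryCatch(
    frame_to_slot_range(par$frame_lo, par$frame_hi, par$slot_minutes, S),
    error = function(e) c(1L, 0L))
  blocked <- integer(0)
  for (j in seq_len(Kn)) {
    u <- instance$linacs$unavailable[[j]]
    if (!is.null(u) && nrow(u) > 0)
      blocked <- c(blocked,
                   ((as.integer(u[, 1]) - 1L) * S +
                      (as.integer(u[, 2]) - 1L)) * Kn + j)
  }
  nP <- nrow(instance$patients)
  opts <- lapply(seq_len(nP), patient_options, instance = instance,
                 frame_range = frame_range, blocked = blocked,
                 guard = guard)
  counts <- lengths(opts)
  if (any(counts == 0))
    return(list(status = "infeasible", objective = NA_real_))
  if (prod(counts) > guard) oracle_too_large(prod(counts), guard)
  ord <- order(counts)
  occ <- array(FALSE, dim = c(Kn, Tn, S))
  new_starts <- matrix(0L, Kn, Tn)
  is_new <- instance$patients$is_new
  p_dur <- instance$patients$duration_slots
  best <- Inf
  dfs <- function(pos, cost) {
    if (cost >= best) return(invisible())
    if (pos > nP) {
      best <<- cost
      return(invisible())
    }
    i <- ord[pos]
    for (o in opts[[i]]) {
      if (cost + o$cost >= best) next
      free <- TRUE
      for (d in seq_along(o$days)) {
        span <- o$slots[d]:(o$slots[d] + p_dur[i] - 1L)
        if (any(occ[o$k, o$days[d], span])) { free <- FALSE; break }
      }
      if (!free) next
      if (is_new[i] &&
          new_starts[o$k, o$days[1]] + 1L > par$max_new_starts) next
      for (d in seq_along(o$days))
        occ[o$k, o$days[d],
            o$slots[d]:(o$slots[d] + p_dur[i] - 1L)] <<- TRUE
      if (is_new[i])
        new_starts[o$k, o$days[1]] <<- new_starts[o$k, o$days[1]] + 1L
      dfs(pos + 1L, cost + o$cost)
      for (d in seq_along(o$days))
        occ[o$k, o$days[d],
            o$slots[d]:(o$slots[d] + p_dur[i] - 1L)] <<- FALSE
      if (is_new[i])
        new_starts[o$k, o$days[1]] <<- new_starts[o$k, o$days[1]] - 1L
    }
    invisible()
  }
  dfs(1L, 0)
  if (is.infinite(best)) list(status = "infeasible", objective = NA_real_)
  else list(status = "optimal", objective = best)
}
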