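# Greedy workload-balancing pre-assignment of new patients to linacs, and
# the cluster decomposition that splits a center's machines into groups
# solved as independent subproblems. Ongoing patients stay on the machine
# they are being treated on; new patients are placed, one at a time, on
# the least-loaded feasible machine that still has room for their weekly
# volume.

#' Expected weekly session minutes of a patient
#'
#' The number of sessions the patient can receive within the horizon when
#' starting on day 1 (every `spacing_days` days, up to the remaining
#' session count), times the session duration in minutes.
#'
#' @param patient A one-row patient data frame.
#' @param params An [rt_params()] object.
#' @return Minutes of session time, a single number.
#' @export
patient_volume <- function(patient, params) {
  days <- required_session_days(1L, patient$spacing_days,
                                patient$sessions, params$horizon_days)
  length(days) * patient$duration_slots * params$slot_minutes
}

patient_volumes <- function(instance) {
  vapply(seq_len(nrow(instance$patients)), function(i)
    patient_volume(instance$patients[i, ], instance$params), numeric(1))
}

#' Initial linac workloads from ongoing patients
#'
#' @param instance An `rt_instance`.
#' @return Named numeric vector: minutes of session volume already
#'   committed to each linac by patients undergoing treatment.
#' @export
initial_workloads <- function(instance) {
  wl <- stats::setNames(rep(0, nrow(instance$linacs)), instance$linacs$id)
  vols <- patient_volumes(instance)
  ongoing <- which(!instance$patients$is_new)
  for (i in ongoing) {
    k <- instance$patients$current_linac[i]
    wl[k] <- wl[k] + vols[i]
  }
  wl
}

#' Greedy workload-balancing patient-to-linac pre-assignment
#'
#' Processes new patients in input order (optionally in decreasing volume
#' order). For each patient, the feasible linacs are scanned in increasing
#' order of current workload (ties broken by linac id) and the patient is
#' placed on the first machine whose capacity still accommodates the
#' patient's volume. Assumes total volume fits total capacity; if a
#' patient fits nowhere, a `rt_preassign_infeasible` error names them.
#'
#' @param instance An `rt_instance`.
#' @param order `"input"` (default) or `"volume"` (largest first, the
#'   classic longest-processing-time refinement).
#' @return An `rt_preassignment`: `assignment` (named character vector,
#'   patient id to linac id, covering all patients) and `workloads`
#'   (minutes per linac).
#' @export
preassign <- function(instance, order = c("input", "volume")) {
  order <- match.arg(order)
  pts <- instance$patients
  vols <- patient_volumes(instance)
  wl <- initial_workloads(instance)
  cap <- stats::setNames(instance$linacs$capacity_min, instance$linacs$id)
  assignment <- stats::setNames(pts$current_linac, pts$id)
  new_idx <- which(pts$is_new)
  if (order == "volume")
    new_idx <- new_idx[base::order(-vols[new_idx])]
  for (i in new_idx) {
    kset <- pts$feasible_linacs[[i]]
    kset <- kset[base::order(wl[kset], kset)]
    placed <- FALSE
    for (k in kset) {
      if (wl[k] + vols[i] <= cap[k]) {
        assignment[pts$id[i]] <- k
        wl[k] <- wl[k] + vols[i]
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(structure(
        class = c("rt_preassign_infeasible", "error", "condition"),
        list(message = paste0("pre-assignment infeasible: patient ",
                              pts$id[i], " (volume ", vols[i],
                              " min) fits no feasible linac"),
             call = sys.call(-1))))
  }
  structure(list(assignment = assignment, workloads = wl),
            class = "rt_preassignment")
}

#' @export
print.rt_preassignment <- function(x, ...) {
  cat("Pre-assignment of", length(x$assignment), "patients\n")
  print(data.frame(linac = names(x$workloads),
                   workload_min = as.numeric(x$workloads),
                   n_patients = as.integer(
                     table(factor(x$assignment,
                                  levels = names(x$workloads)))),
                   row.names = NULL))
  invisible(x)
}

#' Validate a cluster specification
#'
#' @param spec List of character vectors of linac ids.
#' @param linacs Linac table of the instance.
#' @return `spec`, invisibly, or an error of class `rt_cluster_spec_error`.
#' @export
validate_cluster_spec <- function(spec, linacs) {
  fail <- function(msg) stop(structure(
    class = c("rt_cluster_spec_error", "error", "condition"),
    list(message = paste0("invalid cluster spec: ", msg),
         call = sys.call(-1))))
  ids <- unlist(spec, use.names = FALSE)
  if (anyDuplicated(ids)) fail("a linac appears in two clusters")
  if (!setequal(ids, linacs$id))
    fail("clusters must partition the full set of linacs")
  for (cl in spec) {
    loc <- unique(linacs$location[match(cl, linacs$id)])
    if (length(loc) > 1)
      fail("a cluster mixes main and satellite locations")
  }
  invisible(spec)
}

#' Split an instance into per-cluster subinstances
#'
#' Each subinstance keeps the cluster's linacs and the patients whose
#' pre-assigned machine belongs to the cluster. Within a cluster, a new
#' patient may still be moved to any feasible machine of that cluster
#' (their feasible set is intersected with it); ongoing patients remain
#' pinned to their current machine.
#'
#' @param instance An `rt_instance`.
#' @param preassignment An `rt_preassignment` covering all patients.
#' @param spec List of character vectors of linac ids; must partition the
#'   linacs without mixing main and satellite locations.
#' @return A list of `rt_instance` objects, one per cluster, in spec
#'   order.
#' @export
partition_clusters <- function(instance, preassignment, spec) {
  validate_cluster_spec(spec, instance$linacs)
  asg <- preassignment$assignment
  if (!all(instance$patients$id %in% names(asg)) ||
      anyNA(asg[instance$patients$id]))
    stop("pre-assignment does not cover every patient")
  lapply(spec, function(cl) {
    kidx <- match(cl, instance$linacs$id)
    keep <- which(asg[instance$patients$id] %in% cl)
    pts <- instance$patients[keep, , drop = FALSE]
    pts$feasible_linacs <- lapply(pts$feasible_linacs, intersect, y = cl)
    rownames(pts) <- NULL
    rt_instance(pts, instance$linacs[kidx, , drop = FALSE],
                instance$params)
  })
}

#' Single-linac and location-based cluster specs
#'
#' Convenience constructors: `clusters_singleton()` puts every linac in
#' its own cluster; `clusters_by_location()` pairs machines within each
#' location into clusters of the requested size.
#'
#' @param instance An `rt_instance`.
#' @param size Linacs per cluster for `clusters_by_location()`.
#' @return A cluster spec (list of character vectors).
#' @export
clusters_singleton <- function(instance) {
  as.list(instance$linacs$id)
}

#' @rdname clusters_singleton
#' @export
clusters_by_location <- function(instance, size = 2L) {
  out <- list()
  for (loc in unique(instance$linacs$location)) {
    ids <- instance$linacs$id[instance$linacs$location == loc]
    grp <- split(ids, ceiling(seq_along(ids) / size))
    out <- c(out, unname(grp))
  }
  out
}
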