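# Sensitivity-experiment runner: sweeps the size of the morning and
# late-day preference windows and the probability split over the three
# windows, re-generating and re-solving an instance per cell.

#' Build a sensitivity experiment grid
#'
#' Each cell widens the morning window to `[0, size]` and the late window
#' to `[day_end - size, day_end]` (the midday window is unchanged) and
#' sets the probability split over the morning/midday/late windows.
#'
#' @param window_sizes Sizes in minutes of the morning and late windows
#'   (default 90, 120, 150).
#' @param prob_splits List of length-3 probability vectors over the
#'   morning/midday/late windows.
#' @param seeds Integer vector of generator seeds (one run per seed per
#'   cell).
#' @return A data frame with one row per (window size, split, seed) cell.
#' @export
experiment_grid <- function(window_sizes = c(90, 120, 150),
                            prob_splits = list(c(.25, .50, .25),
                                               c(.50, .25, .25),
                                               c(.125, .75, .125)),
                            seeds = 1L) {
  cells <- expand.grid(size = window_sizes,
                       split = seq_along(prob_splits),
                       seed = seeds, KEEP.OUT.ATTRS = FALSE)
  cells$probs <- prob_splits[cells$split]
  cells$split <- vapply(cells$probs, paste, character(1), collapse = "/")
  cells
}

#' Run a window-preference sensitivity experiment
#'
#' For every grid cell: apply the window deltas to the base generator
#' configuration, generate an instance under the cell seed, run the
#' pre-assignment + cluster + MILP pipeline, and collect the schedule
#' metrics. Failures in a cell are recorded and the sweep continues.
#'
#' @param grid A data frame from [experiment_grid()].
#' @param base_config Base `rt_gen_config`.
#' @param clusters Cluster spec passed to [solve_sequential()], or
#'   `"none"`.
#' @param time_limit_s,gap_tol Solver parameters per cell run.
#' @return A data frame with one row per cell: window size, probability
#'   split, seed, solve status, objective (total deviation minutes),
#'   sessions scheduled, percentage outside the window and the mean
#'   deviation of out-of-window sessions.
#' @export
run_experiment <- function(grid = experiment_grid(),
                           base_config = default_nki_config(),
                           clusters = "none", time_limit_s = 7200,
                           gap_tol = 1e-4) {
  day_end <- base_config$params$slots_per_day *
    base_config$params$slot_minutes
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cfg <- base_config
    size <- grid$size[r]
    probs <- grid$probs[[r]]
    cfg$window_menu[[1]]$window <- c(0, size)
    cfg$window_menu[[3]]$window <- c(day_end - size, day_end)
    for (w in 1:3) cfg$window_menu[[w]]$prob <- probs[w]
    cfg$seed <- as.integer(grid$seed[r])
    res <- tryCatch({
      inst <- generate_instance(cfg)
      run <- solve_sequential(inst, clusters, time_limit_s = time_limit_s,
                              gap_tol = gap_tol)
      m <- run$metrics
      data.frame(size = size, split = grid$split[r], seed = grid$seed[r],
                 status = run$status, objective = run$objective,
                 sessions = m$sessions_scheduled,
                 pct_outside = 100 * m$fraction_outside,
                 avg_deviation_outside = m$avg_deviation_outside,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(size = size, split = grid$split[r], seed = grid$seed[r],
                 status = paste("error:", conditionMessage(e)),
                 objective = NA_real_, sessions = NA_integer_,
                 pct_outside = NA_real_,
                 avg_deviation_outside = NA_real_,
                 stringsAsFactors = FALSE))
    rows[[r]] <- res
  }
  do.call(rbind, rows)
}
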