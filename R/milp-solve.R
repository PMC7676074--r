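# Solver backend. The model is handed to HiGHS through SciPy's
# scipy.optimize.milp in a short-lived python subprocess: the constraint
# matrix travels as a MatrixMarket file, everything else as JSON. The
# contract is the thin one every MILP backend offers -- variables, linear
# constraints, objective, time limit and relative gap -- so another solver
# can be substituted behind solve_milp() without touching the formulation.

the_solver <- new.env(parent = emptyenv())

find_python <- function() {
  if (!is.null(the_solver$python)) return(the_solver$python)
  for (cand in c("python", "python3")) {
    path <- Sys.which(cand)
    if (nzchar(path)) {
      ok <- suppressWarnings(system2(
        path, c("-c", shQuote("import scipy.optimize, scipy.io")),
        stdout = FALSE, stderr = FALSE))
      if (identical(ok, 0L)) {
        the_solver$python <- path
        return(path)
      }
    }
  }
  NULL
}

solver_unavailable <- function(detail) {
  stop(structure(class = c("rt_solver_unavailable", "error", "condition"),
                 list(message = paste0(
                   "no MILP backend available (needs python with scipy on ",
                   "the PATH): ", detail), call = sys.call(-1))))
}

#' Solve a built scheduling MILP
#'
#' @param model An `rt_milp` from [build_milp()].
#' @param time_limit_s Wall-clock limit for the solver, in seconds.
#' @param gap_tol Relative MIP gap at which the search stops.
#' @return An `rt_solve_report`: `status` (one of `"optimal"`,
#'   `"feasible"`, `"time_limit"`, `"infeasible"`), `objective` (total
#'   deviation minutes; present for optimal/feasible), `gap`, `wall_time`
#'   seconds and the raw variable `values`.
#' @export
solve_milp <- function(model, time_limit_s = 7200, gap_tol = 1e-4) {
  stopifnot(inherits(model, "rt_milp"))
  python <- find_python()
  if (is.null(python))
    solver_unavailable("python interpreter with scipy not found")
  script <- system.file("python", "milp_solve.py", package = "rtsched")
  if (!nzchar(script)) solver_unavailable("bundled solver runner missing")

  dir <- tempfile("rtmilp")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  mtx <- file.path(dir, "A.mtx")
  Matrix::writeMM(methods::as(model$A, "TsparseMatrix"), mtx)
  cap <- function(z) { # JSON has no Inf; the runner restores |z| >= 1e30
    z[z == Inf] <- 1e30
    z[z == -Inf] <- -1e30
    z
  }
  spec <- list(
    matrix = mtx,
    nrows = nrow(model$A), ncols = ncol(model$A),
    obj = model$obj, lb = cap(model$lb), ub = cap(model$ub),
    integrality = model$integrality,
    row_lb = cap(model$row_lb), row_ub = cap(model$row_ub),
    time_limit = time_limit_s, mip_rel_gap = gap_tol,
    out = file.path(dir, "result.json")
  )
  spec_path <- file.path(dir, "spec.json")
  jsonlite::write_json(spec, spec_path, auto_unbox = TRUE, digits = NA)
  status <- suppressWarnings(system2(python, c(script, spec_path),
                                     stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status")
  if (!is.null(code) && code != 0)
    solver_unavailable(paste(status, collapse = "\n"))
  res <- jsonlite::read_json(spec$out, simplifyVector = TRUE)
  report <- list(
    status = res$status,
    objective = if (!is.null(res$objective)) res$objective else NA_real_,
    gap = if (!is.null(res$gap)) res$gap else NA_real_,
    wall_time = res$wall_time,
    values = if (!is.null(res$x)) as.numeric(res$x) else NULL
  )
  class(report) <- "rt_solve_report"
  report
}

#' @export
print.rt_solve_report <- function(x, ...) {
  cat(sprintf("Solve report: status %s", x$status))
  if (!is.na(x$objective))
    cat(sprintf(", objective %g min (gap %.2g)", x$objective, x$gap))
  cat(sprintf(", %.2f s\n", x$wall_time))
  invisible(x)
}

#' Extract the booked schedule from a solved model
#'
#' @param model The `rt_milp` that was solved.
#' @param report The `rt_solve_report` returned by [solve_milp()].
#' @param tol Integrality tolerance on the binary variables.
#' @return An `rt_schedule` (one row per booked session, with start
#'   minutes and window deviations attached).
#' @export
extract_schedule <- function(model, report, tol = 1e-6) {
  if (!report$status %in% c("optimal", "feasible"))
    stop("no incumbent solution to extract (status ", report$status, ")")
  vals <- report$values
  if (is.null(vals) || length(vals) != length(model$obj))
    stop("extraction error: solution vector missing or of wrong length")
  bin <- vals[seq_len(model$n_x + model$n_y)]
  if (any(abs(bin - round(bin)) > tol))
    stop("extraction error: fractional binary values beyond tolerance")
  on <- which(round(vals[seq_len(model$n_x)]) == 1)
  pts <- model$instance$patients
  lns <- model$instance$linacs
  xv <- model$xvars[on, , drop = FALSE]
  sessions <- data.frame(
    patient = pts$id[xv$p],
    linac = lns$id[xv$k],
    day = xv$t,
    start_slot = xv$s,
    stringsAsFactors = FALSE
  )
  rt_schedule(sessions, model$instance)
}

#' Export a built model in CPLEX LP text format
#'
#' Audit dump for inspecting the generated rows; every row carries its
#' constraint-family tag in its name.
#'
#' @param model An `rt_milp`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lp <- function(model, path) {
  At <- methods::as(model$A, "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  vn <- function(j) paste0("v", j)
  writeLines("Minimize", con)
  objterms <- which(model$obj != 0)
  writeLines(paste(" obj:", paste(sprintf("%+g %s", model$obj[objterms],
                                          vn(objterms)), collapse = " ")),
             con)
  writeLines("Subject To", con)
  rows <- split(data.frame(j = At@j + 1L, x = At@x),
                factor(At@i + 1L, levels = seq_len(nrow(model$A))))
  for (r in seq_along(rows)) {
    terms <- rows[[r]]
    lhs <- paste(sprintf("%+g %s", terms$x, vn(terms$j)), collapse = " ")
    lbv <- model$row_lb[r]; ubv <- model$row_ub[r]
    nm <- sprintf("%s_r%d", model$family[r], r)
    if (is.finite(ubv))
      writeLines(sprintf(" %s: %s <= %g", nm, lhs, ubv), con)
    if (is.finite(lbv))
      writeLines(sprintf(" %s_lb: %s >= %g", nm, lhs, lbv), con)
  }
  writeLines("Bounds", con)
  for (j in which(model$integrality == 0L))
    writeLines(sprintf(" 0 <= %s <= +inf", vn(j)), con)
  writeLines("Binaries", con)
  writeLines(paste("", paste(vn(which(model$integrality == 1L)),
                             collapse = " ")), con)
  writeLines("End", con)
  invisible(path)
}
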