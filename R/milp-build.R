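# Mixed-integer model builder. Decision variables:
#   x[i,k,s,t] = 1 if patient i gets a session starting at slot s of
#                linac k on day t (binary),
#   y[i,k,t]   = 1 if new patient i starts treatment on linac k, day t
#                (binary, new patients only),
#   dev_lo[i,t], dev_hi[i,t] >= 0: minutes by which the session start of
#                patient i on day t falls before/after the preferred
#                window (continuous).
# The objective minimizes the total window deviation over all patients
# and days. Constraint families keep the tags eq2..eq16 for auditing:
#   eq2/eq3  session continuity: once a first session is placed, sessions
#            recur every b_i days on the same linac until I_i sessions or
#            the horizon end;
#   eq4      no session on the off days of spaced (b_i >= 2) schemes;
#   eq5      at most one session per patient per day;
#   eq6      at most I_i sessions in the horizon;
#   eq7      the first session falls on or before the due day;
#   eq8      at most one session *starts* in any available slot (blocked
#            slots get no variables);
#   eq10/eq11 link y to treatment starts of new patients;
#   eq12     at most max_new_starts new patients start per linac-day;
#   eq13     the slots a session occupies after its start cannot be the
#            start of any other session on that linac-day;
#   eq16     deviation variables absorb starts outside the window.
# eq9 (feasible linacs), eq14 (no starts that would run past the day end)
# and eq15 (restricted staff-presence frame) are realized by not creating
# the corresponding x variables, which is equivalent to fixing them to 0;
# the build reports per-family counts of variables eliminated this way.

#' Build the scheduling MILP for an instance
#'
#' @param instance A validated `rt_instance`.
#' @param fixed_assignment Optional named character vector mapping patient
#'   ids to linac ids (e.g. from [preassign()]); when given, each mapped
#'   patient's feasible set is tightened to that single machine. Ongoing
#'   patients are always pinned to their current linac.
#' @return An object of class `rt_milp`: the sparse constraint system, the
#'   objective, bounds and integrality, the variable index tables
#'   (`xvars`, `yvars`), per-row family tags and per-family counts of
#'   eliminated variables.
#' @export
build_milp <- function(instance, fixed_assignment = NULL) {
  v <- validate_instance(instance)
  if (nrow(v) > 0)
    stop("build refused, instance fails validation: ",
         paste(v$message, collapse = "; "))
  pts <- instance$patients
  lns <- instance$linacs
  par <- instance$params
  S <- par$slots_per_day
  Tn <- par$horizon_days
  Kn <- nrow(lns)
  nP <- nrow(pts)
  l <- par$slot_minutes

  blocked_key <- integer(0)
  kst_key <- function(k, s, t) ((t - 1L) * S + (s - 1L)) * Kn + k
  for (j in seq_len(Kn)) {
    u <- lns$unavailable[[j]]
    if (!is.null(u) && nrow(u) > 0)
      blocked_key <- c(blocked_key, kst_key(j, as.integer(u[, 2]),
                                            as.integer(u[, 1])))
  }

  frame_range <- tryCatch(
    frame_to_slot_range(par$frame_lo, par$frame_hi, l, S),
    error = function(e) NULL)

  eliminated <- c(eq9 = 0L, eq14 = 0L, eq15 = 0L, availability = 0L)

  # ---- x variables -------------------------------------------------------
  xs <- vector("list", nP)
  for (i in seq_len(nP)) {
    kset <- pts$feasible_linacs[[i]]
    if (!pts$is_new[i]) {
      fk <- if (is.null(fixed_assignment)) NA_character_
      else unname(fixed_assignment[pts$id[i]])
      if (!is.na(fk) && fk != pts$current_linac[i])
        stop("fixed assignment for ongoing patient ", pts$id[i],
             " contradicts the current linac")
      kset <- pts$current_linac[i]
    } else if (!is.null(fixed_assignment) &&
               !is.na(fixed_assignment[pts$id[i]])) {
      fk <- unname(fixed_assignment[pts$id[i]])
      if (!(fk %in% kset))
        stop("fixed assignment for ", pts$id[i],
             " is outside the patient's feasible linac set")
      kset <- fk
    }
    kidx <- match(kset, lns$id)
    eliminated["eq9"] <- eliminated["eq9"] + (Kn - length(kidx)) * S * Tn
    p_i <- pts$duration_slots[i]
    s_hi <- S - p_i + 1L
    eliminated["eq14"] <- eliminated["eq14"] +
      length(kidx) * (S - s_hi) * Tn
    s_seq <- seq_len(s_hi)
    if (pts$restricted_frame[i]) {
      if (is.null(frame_range))
        stop("restricted frame admits no start slot")
      keep <- s_seq >= frame_range[1] & s_seq <= frame_range[2]
      eliminated["eq15"] <- eliminated["eq15"] +
        length(kidx) * sum(!keep) * Tn
      s_seq <- s_seq[keep]
    }
    if (length(s_seq) == 0)
      stop("patient ", pts$id[i], " has no admissible start slot")
    g <- expand.grid(k = kidx, s = s_seq, t = seq_len(Tn),
                     KEEP.OUT.ATTRS = FALSE)
    g$p <- i
    xs[[i]] <- g
  }
  xv <- do.call(rbind, xs)
  if (length(blocked_key) > 0) {
    bk <- kst_key(xv$k, xv$s, xv$t) %in% blocked_key
    eliminated["availability"] <- sum(bk)
    xv <- xv[!bk, , drop = FALSE]
  }
  xv$col <- seq_len(nrow(xv))
  nx <- nrow(xv)

  # ---- y variables (new patients) ---------------------------------------
  ypairs <- unique(xv[xv$p %in% which(pts$is_new), c("p", "k")])
  if (nrow(ypairs) > 0) {
    yv <- ypairs[rep(seq_len(nrow(ypairs)), each = Tn), , drop = FALSE]
    yv$t <- rep(seq_len(Tn), nrow(ypairs))
  } else {
    yv <- data.frame(p = integer(), k = integer(), t = integer())
  }
  yv$col <- nx + seq_len(nrow(yv))
  ny <- nrow(yv)

  # ---- deviation variables ----------------------------------------------
  dlo_col <- function(p, t) nx + ny + (p - 1L) * Tn + t
  dhi_col <- function(p, t) nx + ny + nP * Tn + (p - 1L) * Tn + t
  ncol_total <- nx + ny + 2L * nP * Tn

  # ---- constraint accumulator -------------------------------------------
  tri_r <- vector("list", 0); tri_c <- vector("list", 0)
  tri_v <- vector("list", 0)
  row_lb <- vector("list", 0); row_ub <- vector("list", 0)
  fam <- vector("list", 0)
  nrows <- 0L
  add_block <- function(r, c, v, lb, ub, family) {
    # r is 1-based within the block, one lb/ub per block row
    n <- length(lb)
    tri_r[[length(tri_r) + 1L]] <<- r + nrows
    tri_c[[length(tri_c) + 1L]] <<- c
    tri_v[[length(tri_v) + 1L]] <<- v
    row_lb[[length(row_lb) + 1L]] <<- lb
    row_ub[[length(row_ub) + 1L]] <<- ub
    fam[[length(fam) + 1L]] <<- rep(family, n)
    nrows <<- nrows + n
  }

  # day groups: columns of x summed over s, per (p, k, t)
  pkt_key <- ((xv$p - 1L) * Kn + (xv$k - 1L)) * Tn + xv$t
  day_groups <- split(xv$col, pkt_key)
  dg <- function(p, k, t) {
    g <- day_groups[[as.character(((p - 1L) * Kn + (k - 1L)) * Tn + t)]]
    if (is.null(g)) integer(0) else g
  }
  pk_pairs <- unique(xv[, c("p", "k")])

  # eq2/eq3: continuity; eq4: off days of spaced schemes
  for (q in seq_len(nrow(pk_pairs))) {
    p <- pk_pairs$p[q]; k <- pk_pairs$k[q]
    b <- pts$spacing_days[p]; I <- pts$sessions[p]
    for (t in seq_len(Tn)[-1]) {
      hi <- min(Tn, t + b * (I - 1L))
      if (t + b <= hi) {
        prev <- unlist(lapply(seq_len(t - 1L), dg, p = p, k = k),
                       use.names = FALSE)
        cur <- dg(p, k, t)
        for (n in seq.int(t + b, hi, by = b)) {
          gn <- dg(p, k, n)
          cols <- c(cur, prev, gn)
          vals <- c(rep(1, length(cur)), rep(-1, length(prev)),
                    rep(-1, length(gn)))
          add_block(rep(1L, length(cols)), cols, vals, -Inf, 0, "eq2")
        }
      }
    }
    hi <- min(Tn, b * (I - 1L) + 1L)
    if (b + 1L <= hi) {
      g1 <- dg(p, k, 1L)
      for (n in seq.int(b + 1L, hi, by = b)) {
        gn <- dg(p, k, n)
        cols <- c(g1, gn)
        vals <- c(rep(1, length(g1)), rep(-1, length(gn)))
        add_block(rep(1L, length(cols)), cols, vals, -Inf, 0, "eq3")
      }
    }
    if (b >= 2L && Tn - b >= 1L) {
      for (t in seq_len(Tn - b)) {
        gt <- dg(p, k, t)
        for (n in seq.int(t + 1L, t + b - 1L)) {
          gn <- dg(p, k, n)
          cols <- c(gt, gn)
          add_block(rep(1L, length(cols)), cols, rep(1, length(cols)),
                    -Inf, 1, "eq4")
        }
      }
    }
  }

  # eq5: one session per patient per day
  pt_key <- (xv$p - 1L) * Tn + xv$t
  for (g in split(xv$col, pt_key))
    add_block(rep(1L, length(g)), g, rep(1, length(g)), -Inf, 1, "eq5")

  # eq6: at most I_i sessions
  for (p in seq_len(nP)) {
    g <- xv$col[xv$p == p]
    add_block(rep(1L, length(g)), g, rep(1, length(g)), -Inf,
              pts$sessions[p], "eq6")
  }

  # eq7: treatment starts by the due day
  for (p in seq_len(nP)) {
    g <- xv$col[xv$p == p & xv$t <= pts$due_day[p]]
    if (length(g) == 0)
      stop("patient ", pts$id[p],
           " cannot start by the due day: no admissible slot")
    add_block(rep(1L, length(g)), g, rep(1, length(g)), 1, Inf, "eq7")
  }

  # eq8: at most one session starts per available slot
  kst <- kst_key(xv$k, xv$s, xv$t)
  kst_groups <- split(xv$col, kst)
  for (g in kst_groups)
    add_block(rep(1L, length(g)), g, rep(1, length(g)), -Inf, 1, "eq8")

  # eq10/eq11: y counts treatment starts of new patients
  if (ny > 0) {
    for (r in seq_len(ny)) {
      p <- yv$p[r]; k <- yv$k[r]; t <- yv$t[r]
      gt <- dg(p, k, t)
      if (t == 1L) {
        cols <- c(yv$col[r], gt)
        vals <- c(1, rep(-1, length(gt)))
        add_block(rep(1L, length(cols)), cols, vals, 0, Inf, "eq11")
      } else {
        tp <- max(1L, t - pts$spacing_days[p])
        gp <- dg(p, k, tp)
        cols <- c(yv$col[r], gt, gp)
        vals <- c(1, rep(-1, length(gt)), rep(1, length(gp)))
        add_block(rep(1L, length(cols)), cols, vals, 0, Inf, "eq10")
      }
    }
    # eq12: cap on new starts per linac-day
    kt_key <- (yv$k - 1L) * Tn + yv$t
    for (g in split(yv$col, kt_key))
      add_block(rep(1L, length(g)), g, rep(1, length(g)), -Inf,
                par$max_new_starts, "eq12")
  }

  # eq13: occupied trailing slots block other starts (vectorized)
  heads <- xv[pts$duration_slots[xv$p] >= 2L, , drop = FALSE]
  if (nrow(heads) > 0) {
    reps <- pts$duration_slots[heads$p] - 1L
    hidx <- rep(seq_len(nrow(heads)), reps)
    off <- sequence(reps)
    tail_key <- kst_key(heads$k[hidx], heads$s[hidx] + off, heads$t[hidx])
    gsel <- kst_groups[as.character(tail_key)]
    glen <- lengths(gsel)
    keep <- glen > 0
    if (any(keep)) {
      hcol <- heads$col[hidx][keep]
      gsel <- gsel[keep]
      glen <- glen[keep]
      nr <- length(hcol)
      r <- c(seq_len(nr), rep(seq_len(nr), glen))
      cc <- c(hcol, unlist(gsel, use.names = FALSE))
      add_block(r, cc, rep(1, length(cc)), rep(-Inf, nr), rep(1, nr),
                "eq13")
    }
  }

  # eq16: window deviation linking (only rows not dominated by dev >= 0)
  start_min <- l * (xv$s - 1)
  lo_coef <- pts$window_lo[xv$p] - start_min
  sel <- which(lo_coef > 0)
  if (length(sel) > 0) {
    nr <- length(sel)
    r <- rep(seq_len(nr), 2L)
    cc <- c(xv$col[sel], dlo_col(xv$p[sel], xv$t[sel]))
    vals <- c(lo_coef[sel], rep(-1, nr))
    add_block(r, cc, vals, rep(-Inf, nr), rep(0, nr), "eq16")
  }
  hi_coef <- start_min - pts$window_hi[xv$p]
  sel <- which(hi_coef > 0)
  if (length(sel) > 0) {
    nr <- length(sel)
    r <- rep(seq_len(nr), 2L)
    cc <- c(xv$col[sel], dhi_col(xv$p[sel], xv$t[sel]))
    vals <- c(hi_coef[sel], rep(-1, nr))
    add_block(r, cc, vals, rep(-Inf, nr), rep(0, nr), "eq16")
  }

  A <- Matrix::sparseMatrix(
    i = unlist(tri_r, use.names = FALSE),
    j = unlist(tri_c, use.names = FALSE),
    x = unlist(tri_v, use.names = FALSE),
    dims = c(nrows, ncol_total))

  obj <- c(rep(0, nx + ny), rep(1, 2L * nP * Tn))
  lb <- rep(0, ncol_total)
  ub <- c(rep(1, nx + ny), rep(Inf, 2L * nP * Tn))
  integrality <- c(rep(1L, nx + ny), rep(0L, 2L * nP * Tn))

  structure(list(
    A = A,
    row_lb = unlist(row_lb, use.names = FALSE),
    row_ub = unlist(row_ub, use.names = FALSE),
    family = unlist(fam, use.names = FALSE),
    obj = obj, lb = lb, ub = ub, integrality = integrality,
    xvars = xv, yvars = yv,
    n_x = nx, n_y = ny, n_patients = nP, horizon = Tn,
    dlo_offset = nx + ny, dhi_offset = nx + ny + nP * Tn,
    eliminated = eliminated,
    instance = instance
  ), class = "rt_milp")
}

#' @export
print.rt_milp <- function(x, ...) {
  cat(sprintf("Scheduling MILP: %d binaries (%d x, %d y), %d deviation vars\n",
              x$n_x + x$n_y, x$n_x, x$n_y, 2L * x$n_patients * x$horizon))
  tab <- table(x$family)
  cat(sprintf("  %d constraint rows: %s\n", length(x$family),
              paste(names(tab), as.integer(tab), sep = "=",
                    collapse = ", ")))
  el <- x$eliminated
  cat(sprintf("  variables eliminated: %s\n",
              paste(names(el), as.integer(el), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Per-family constraint row counts of a built model
#'
#' @param model An `rt_milp`.
#' @return Named integer vector of row counts by constraint family.
#' @export
constraint_counts <- function(model) {
  tab <- table(model$family)
  stats::setNames(as.integer(tab), names(tab))
}
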