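# Fixture builders. Everything is generated in code; random fixtures are
# seeded so failures reproduce.

# a 2-day, 4-slot, single-linac instance with two patients
tiny_instance <- function() {
  params <- rt_params(horizon_days = 2, slots_per_day = 4,
                      slot_minutes = 5, max_new_starts = 6,
                      frame_lo = 0, frame_hi = 15)
  rt_instance(
    rt_patients(id = c("a", "b"), sessions = c(2, 1), due_day = c(1, 2),
                duration_slots = c(1, 2), window_lo = c(0, 0),
                window_hi = c(0, 20),
                feasible_linacs = list("L1", "L1")),
    rt_linacs("L1", params = params), params)
}

# random tiny instance within the enumeration oracle's comfort zone:
# <= 3 patients, <= 2 linacs, <= 2 days, <= 8 slots
random_tiny_instance <- function(seed) {
  set.seed(seed)
  Tn <- sample(1:2, 1)
  S <- sample(4:8, 1)
  Kn <- sample(1:2, 1)
  nP <- sample(1:3, 1)
  l <- 5
  params <- rt_params(horizon_days = Tn, slots_per_day = S,
                      slot_minutes = l, max_new_starts = 6,
                      frame_lo = l, frame_hi = (S - 1) * l)
  lin_ids <- paste0("L", seq_len(Kn))
  pts <- do.call(rbind, lapply(seq_len(nP), function(i) {
    p_i <- sample(1:2, 1)
    I <- sample(1:2, 1)
    is_new <- runif(1) < 0.6
    lo <- sample(0:(S - p_i), 1) * l
    hi <- min(lo + sample(0:3, 1) * l, (S - 1) * l)
    rt_patients(
      id = paste0("p", i),
      sessions = I,
      due_day = sample(seq_len(Tn), 1),
      duration_slots = p_i,
      spacing_days = sample(1:2, 1),
      window_lo = lo, window_hi = hi,
      feasible_linacs = list(lin_ids),
      current_linac = if (is_new) NA_character_ else
        lin_ids[sample(Kn, 1)],
      is_new = is_new,
      restricted_frame = runif(1) < 0.3
    )
  }))
  pts$due_day[!pts$is_new] <- 1L
  rt_instance(pts, rt_linacs(lin_ids, params = params), params)
}

# n patients with full-day windows on k linacs (always window-satisfiable)
full_window_instance <- function(seed, n = 8, k = 1, Tn = 5, S = 30) {
  set.seed(seed)
  params <- rt_params(horizon_days = Tn, slots_per_day = S,
                      slot_minutes = 5, max_new_starts = 6,
                      frame_lo = 0, frame_hi = (S - 1) * 5)
  lin_ids <- paste0("L", seq_len(k))
  pts <- do.call(rbind, lapply(seq_len(n), function(i) {
    rt_patients(
      id = sprintf("p%02d", i),
      sessions = sample(1:Tn, 1),
      due_day = sample(seq_len(Tn), 1),
      duration_slots = sample(1:3, 1),
      window_lo = 0, window_hi = (S - 1) * 5,
      feasible_linacs = list(lin_ids))
  }))
  rt_instance(pts, rt_linacs(lin_ids, params = params), params)
}

# a 25-session single-linac week: 5 patients x 5 daily sessions, packed
# back to back; patient windows chosen so exactly `n_outside` of the 25
# session starts fall outside their windows
worked_example_schedule <- function(n_outside = 2) {
  params <- rt_params(horizon_days = 5, slots_per_day = 40,
                      slot_minutes = 5)
  ids <- paste0("p", 1:5)
  starts <- 1L + 4L * (0:4)       # slots 1,5,9,13,17 -> 0,20,40,60,80 min
  pts <- rt_patients(id = ids, sessions = 5, due_day = 1,
                     duration_slots = 4,
                     window_lo = slot_start_minutes(starts, 5),
                     window_hi = slot_start_minutes(starts, 5),
                     feasible_linacs = list(paste0("L", 1)))
  inst <- rt_instance(pts, rt_linacs("L1", params = params), params)
  sess <- expand.grid(patient = ids, day = 1:5, stringsAsFactors = FALSE)
  sess$linac <- "L1"
  sess$start_slot <- starts[match(sess$patient, ids)]
  # displace patient 1 on two days (still non-overlapping: slots 21, 25)
  shift <- which(sess$patient == "p1" & sess$day %in% c(2, 4))
  sess$start_slot[shift] <- c(21L, 25L)[seq_len(n_outside)]
  list(instance = inst, schedule = rt_schedule(sess, inst))
}
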