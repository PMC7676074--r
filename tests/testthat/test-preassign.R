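test_that("patient volume is horizon-limited session minutes", {
  params <- rt_params()   # 5-day horizon, 5-min slots
  vol <- function(I, b, p) patient_volume(
    rt_patients("x", sessions = I, due_day = 1, duration_slots = p,
                spacing_days = b, feasible_linacs = list("L1")), params)
  expect_equal(vol(5, 1, 3), 75)    # 5 daily sessions of 15 min
  expect_equal(vol(10, 2, 3), 45)   # days 1,3,5 -> 3 sessions
  expect_equal(vol(2, 1, 2), 20)    # truncation at the session count
})

test_that("initial workloads accumulate ongoing patients by linac", {
  params <- rt_params()
  lin <- rt_linacs(c("L1", "L2"), params = params)
  mk <- function(id, cur, I) rt_patients(
    id, sessions = I, due_day = 1, duration_slots = 3,
    feasible_linacs = list(c("L1", "L2")), current_linac = cur,
    is_new = is.na(cur))
  inst <- rt_instance(rbind(mk("a", NA, 5)), lin, params)
  expect_equal(unname(initial_workloads(inst)), c(0, 0))
  inst <- rt_instance(rbind(mk("a", "L2", 5), mk("b", NA, 3)), lin, params)
  expect_equal(initial_workloads(inst), c(L1 = 0, L2 = 75))
  inst <- rt_instance(rbind(mk("a", "L2", 5), mk("b", "L2", 2)),
                      lin, params)
  expect_equal(initial_workloads(inst), c(L1 = 0, L2 = 105))
})

test_that("greedy pre-assignment balances workload ascending", {
  params <- rt_params()
  lin <- rt_linacs(c("L1", "L2"), params = params)
  new_pat <- function(id, I = 5, p = 3, feas = c("L1", "L2"))
    rt_patients(id, sessions = I, due_day = 3, duration_slots = p,
                feasible_linacs = list(feas))
  # two identical patients on two empty identical machines: one each
  inst <- rt_instance(rbind(new_pat("a"), new_pat("b")), lin, params)
  pre <- preassign(inst)
  expect_setequal(unname(pre$assignment), c("L1", "L2"))
  expect_equal(unname(pre$workloads), c(75, 75))

  # the less-loaded machine is scanned first
  ongoing <- rt_patients("og", sessions = 7, due_day = 1,
                         duration_slots = 4, spacing_days = 1,
                         feasible_linacs = list(c("L1", "L2")),
                         current_linac = "L1", is_new = FALSE)
  inst <- rt_instance(rbind(ongoing, new_pat("a")), lin, params)
  pre <- preassign(inst)
  expect_identical(unname(pre$assignment["a"]), "L2")
  expect_identical(unname(pre$assignment["og"]), "L1")

  # when the least-loaded machine lacks residual capacity, scan onwards
  lin2 <- rt_linacs(c("L1", "L2"), capacity_min = c(50, 3000),
                    params = params)
  inst <- rt_instance(new_pat("a"), lin2, params)
  expect_identical(unname(preassign(inst)$assignment["a"]), "L2")

  # nothing fits: typed error naming the patient
  lin3 <- rt_linacs(c("L1", "L2"), capacity_min = c(50, 50),
                    params = params)
  inst <- rt_instance(new_pat("a"), lin3, params)
  expect_error(preassign(inst), class = "rt_preassign_infeasible")
  expect_error(preassign(inst), "patient a")
})

test_that("greedy balance: spread within one patient volume", {
  set.seed(41)
  cfg <- default_nki_config(n_patients = 80, n_linacs = 4, seed = 41)
  inst <- generate_instance(cfg)
  inst$patients$is_new <- TRUE          # all-new => equal initial loads
  inst$patients$current_linac <- NA_character_
  inst$patients$due_day <- pmax(inst$patients$due_day, 1L)
  pre <- preassign(inst)
  vols <- vapply(seq_len(nrow(inst$patients)), function(i)
    patient_volume(inst$patients[i, ], inst$params), numeric(1))
  expect_lte(diff(range(pre$workloads)), max(vols))
  expect_true(all(pre$workloads <= inst$linacs$capacity_min))
  expect_true(all(mapply(function(id, k)
    k %in% inst$patients$feasible_linacs[[match(id, inst$patients$id)]],
    names(pre$assignment), pre$assignment)))
})

test_that("cluster partition splits patients and tightens linac sets", {
  cfg <- default_nki_config(n_patients = 40, n_linacs = 8, seed = 13)
  inst <- generate_instance(cfg)
  pre <- preassign(inst)

  subs <- partition_clusters(inst, pre, clusters_singleton(inst))
  expect_length(subs, 8L)
  expect_setequal(unlist(lapply(subs, function(s) s$patients$id)),
                  inst$patients$id)

  spec4 <- list(c("L1", "L3"), c("L2", "L6"), c("L4", "L5"),
                c("L7", "L8"))
  subs <- partition_clusters(inst, pre, spec4)
  expect_length(subs, 4L)
  for (j in seq_along(subs)) {
    expect_setequal(subs[[j]]$linacs$id, spec4[[j]])
    for (i in seq_len(nrow(subs[[j]]$patients)))
      expect_true(all(subs[[j]]$patients$feasible_linacs[[i]] %in%
                        spec4[[j]]))
  }
  ids <- unlist(lapply(subs, function(s) s$patients$id))
  expect_identical(anyDuplicated(ids), 0L)
  expect_setequal(ids, inst$patients$id)

  # satellite and main sites can never share a cluster
  expect_error(
    partition_clusters(inst, pre,
                       list(c("L1", "L7"), c("L2", "L3", "L4", "L5", "L6"),
                            "L8")),
    class = "rt_cluster_spec_error")
  # clusters must partition the machines
  expect_error(partition_clusters(inst, pre, list(c("L1", "L2"))),
               class = "rt_cluster_spec_error")
  expect_error(
    partition_clusters(inst, pre,
                       c(clusters_singleton(inst), list("L1"))),
    class = "rt_cluster_spec_error")
})
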