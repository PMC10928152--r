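test_that("ground truth satisfies its structural invariants", {
  truth <- simulate_ground_truth(tasks = c("a", "b"), n_states = 4,
                                 roi_labels = paste0("R", 1:6),
                                 n_subjects = 5, seed = 42)
  expect_true(validate_ground_truth(truth))
  for (tk in truth$tasks) {
    expect_lt(max(abs(rowSums(truth$transition[[tk]]) - 1)), 1e-12)
    for (S in truth$state_covs[[tk]]) {
      expect_lt(max(abs(S - t(S))), 1e-12)
      expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
  # planted shared state: identical mean/cov across tasks at perturb_sd = 0
  sa <- truth$shared_state_id[["a"]]; sb <- truth$shared_state_id[["b"]]
  expect_equal(truth$state_means[["a"]][sa, ], truth$state_means[["b"]][sb, ])
  expect_equal(truth$state_covs[["a"]][[sa]], truth$state_covs[["b"]][[sb]])
})

test_that("degenerate chains behave as specified", {
  # single state: all hidden labels are 1
  t1 <- simulate_ground_truth(tasks = "a", n_states = 1,
                              roi_labels = paste0("R", 1:3), n_subjects = 2,
                              shared = FALSE, seed = 3)
  ds <- generate_task_dataset(t1, "a", 2, 60)
  expect_true(all(unlist(ds$labels) == 1L))

  # absorbing chain: identity transitions freeze the initial state
  t2 <- simulate_ground_truth(tasks = "a", n_states = 3,
                              roi_labels = paste0("R", 1:3), n_subjects = 3,
                              shared = FALSE, seed = 4)
  t2$transition[["a"]] <- diag(3)
  ds2 <- generate_task_dataset(t2, "a", 3, 80)
  for (z in ds2$labels) expect_equal(length(unique(z)), 1L)

  expect_error(generate_task_dataset(t1, "nope", 1, 60), "unknown task")
  t3 <- t1
  t3$transition[["a"]] <- matrix(2, 1, 1)
  expect_error(generate_task_dataset(t3, "a", 1, 60), "non-stochastic")
})

test_that("long-run occupancy matches the stationary distribution of A", {
  truth <- simulate_ground_truth(tasks = "a", n_states = 4,
                                 roi_labels = paste0("R", 1:4),
                                 n_subjects = 1, shared = FALSE,
                                 occupancy_bias_sd = 0, seed = 7)
  ds <- generate_task_dataset(truth, "a", 1, 2000)
  z <- ds$labels[[1]]
  emp <- tabulate(z, 4) / length(z)
  expect_lt(max(abs(emp - oracle_stationary(truth$transition[["a"]]))), 0.05)
  # empirical transitions match A entrywise
  emp_A <- empirical_transition_matrix(z, 4)
  expect_lt(max(abs(emp_A - truth$transition[["a"]])), 0.05)
})

test_that("occupancy bias tilts the shared-state stationary expectation", {
  truth <- simulate_ground_truth(tasks = c("a", "b"), n_states = 3,
                                 roi_labels = paste0("R", 1:4),
                                 n_subjects = 2, occupancy_bias_sd = 0,
                                 seed = 5)
  truth$subject_occupancy_bias <- c(-1, 1)
  ds <- generate_task_dataset(truth, "a", 2, 2000)
  s <- truth$shared_state_id[["a"]]
  occ <- vapply(ds$labels, function(z) mean(z == s), numeric(1))
  A <- truth$transition[["a"]]
  expected <- vapply(truth$subject_occupancy_bias, function(b) {
    Ab <- A; Ab[, s] <- Ab[, s] * exp(b); Ab <- Ab / rowSums(Ab)
    oracle_stationary(Ab)[s]
  }, numeric(1))
  expect_lt(max(abs(occ - expected)), 0.06)
  expect_gt(occ[2], occ[1])
})

test_that("cohort generation is deterministic and validates its config", {
  cfg <- sim_config(n_subjects = 3, n_timepoints = 60, n_states = 2,
                    roi_labels = paste0("R", 1:4), seed = 11)
  c1 <- generate_multitask_cohort(cfg)
  c2 <- generate_multitask_cohort(cfg)
  expect_identical(c1$runs, c2$runs)
  expect_identical(c1$behavior, c2$behavior)
  expect_error(sim_config(bogus = 1), "unknown config field")
  expect_error(generate_multitask_cohort(sim_config(shared = FALSE,
                                                    behavior_r = 0.5)),
               "without a shared state")
})

test_that("zero behavioral coupling decorrelates index from occupancy", {
  cfg <- sim_config(n_subjects = 200, n_timepoints = 60, n_states = 2,
                    roi_labels = paste0("R", 1:3), behavior_r = 0,
                    seed = 19)
  co <- generate_multitask_cohort(cfg)
  beh <- co$behavior[co$behavior$task == "nback", ]
  expect_lt(abs(cor(beh$shared_occupancy, beh$index)), 0.2)
})

test_that("identical state inventories give zero cross-task KL on the diagonal", {
  truth <- simulate_ground_truth(tasks = c("a", "b"), n_states = 2,
                                 roi_labels = paste0("R", 1:4),
                                 n_subjects = 2, seed = 8)
  truth$state_means[["b"]] <- truth$state_means[["a"]]
  truth$state_covs[["b"]] <- truth$state_covs[["a"]]
  sa <- truth_states(truth, "a"); sb <- truth_states(truth, "b")
  for (k in 1:2) expect_equal(gaussian_kld(sa[[k]], sb[[k]])$jeffreys, 0)
})

test_that("cohort round-trips through its on-disk formats", {
  cfg <- sim_config(n_subjects = 2, n_timepoints = 60, n_states = 2,
                    roi_labels = paste0("R", 1:3), motion_weight = 0.3,
                    seed = 21)
  co <- generate_multitask_cohort(cfg)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  ts_back <- read_roi_ts(file.path(dir, "nback", "sub001_ts.tsv"))
  expect_equal(unname(ts_back$values),
               unname(co$runs$nback$sub001$values), tolerance = 1e-12)
  mo_back <- read_motion(file.path(dir, "nback", "sub001_motion.txt"))
  expect_equal(unname(mo_back$values),
               unname(co$motion$nback$sub001$values), tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  unlink(dir, recursive = TRUE)
})

test_that("race-model trial generation honors the race logic", {
  # stop process far too slow: every stop trial ends in a response
  tr <- generate_race_model_trials(go_mu = 400, go_sd = 50, ssrt_true = 1e6,
                                   n_go = 50, n_stop = 30, seed = 2)
  expect_true(all(tr$responded[tr$trial_type == "stop"]))
  # instantaneous stopping with huge SSD still loses: respond iff go wins
  tr2 <- generate_race_model_trials(go_mu = 400, go_sd = 50, ssrt_true = 0,
                                    n_go = 50, n_stop = 30,
                                    staircase_step = 1, ssd_start = 5000,
                                    seed = 2)
  st <- tr2[tr2$trial_type == "stop", ]
  expect_true(all(st$responded == (st$rt < st$ssd & !is.na(st$rt)) |
                    (!st$responded)))
  # staircase converges near 50% responding
  tr3 <- generate_race_model_trials(seed = 5)
  expect_lt(abs(mean(tr3$responded[tr3$trial_type == "stop"]) - 0.5), 0.1)
})
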