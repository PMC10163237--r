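test_that("stimulus schedules obey run-length and imbalance constraints", {
  for (seed in 1:8) {
    nstim <- if (seed %% 2 == 0) 2 else 4
    task <- task_spec(stimuli = letters[1:nstim])
    tr <- generate_trial_sequence(task, 300, seed = seed)
    expect_lte(max(rle(tr$stimulus)$lengths), 3)
    # prefix imbalance checked by explicit counting
    counts <- matrix(0L, nrow = 300, ncol = nstim,
                     dimnames = list(NULL, letters[1:nstim]))
    for (i in 1:300) {
      if (i > 1) counts[i, ] <- counts[i - 1, ]
      counts[i, tr$stimulus[i]] <- counts[i, tr$stimulus[i]] + 1L
    }
    gaps <- apply(counts, 1, function(r) max(r) - min(r))
    expect_lte(max(gaps), 10)
  }
})

test_that("four-stimulus schedules present each mouse about equally often", {
  task <- task_spec(stimuli = c("a", "b", "c", "d"))
  tr <- generate_trial_sequence(task, 10000, seed = 7)
  freq <- table(tr$stimulus) / 10000
  expect_true(all(abs(freq - 0.25) <= 0.01))
})

test_that("degenerate and determinism contracts of the schedule hold", {
  task <- task_spec()
  expect_error(generate_trial_sequence(task, 0), "n_trials")
  one <- generate_trial_sequence(task, 1, seed = 3)
  expect_equal(nrow(one), 1)
  a <- generate_trial_sequence(task, 200, seed = 42)
  b <- generate_trial_sequence(task, 200, seed = 42)
  expect_identical(a$stimulus, b$stimulus)
  c_ <- generate_trial_sequence(task, 200, seed = 43)
  expect_false(identical(a$stimulus, c_$stimulus))
  # epoch timestamps follow the task timing
  expect_equal(a$t_open_complete - a$t_open, rep(0.4, 200))
  expect_equal(a$t_response - a$t_open, rep(1.3, 200))
  expect_equal(a$t_close - a$t_open, rep(4, 200))
})

test_that("a trained agent produces a high-performance-grade session", {
  task <- task_spec()
  tr <- generate_trial_sequence(task, 400, seed = 1)
  beh <- generate_behavior(tr, agent_params(hit_asymptote = 0.95,
                                            fa_asymptote = 0.05),
                           seed = 2)
  last200 <- beh[201:400, ]
  r <- compute_rates(last200)
  expect_gt(r$hit_rate, 0.8)
  expect_gt(r$cr_rate, 0.8)
  # licks land in the response window on responded trials
  rt <- response_times(beh)
  licked <- !is.na(rt)
  expect_true(all(rt[licked] >= task$grace_s))
})

test_that("an agent that never licks yields only misses and CRs", {
  task <- task_spec()
  tr <- generate_trial_sequence(task, 200, seed = 5)
  never <- agent_params(hit_asymptote = 1e-9, fa_asymptote = 1e-10,
                        midpoint_trial = -1e6)
  beh <- generate_behavior(tr, never, seed = 6)
  expect_true(all(beh$outcome %in% c("miss", "CR")))
  r <- compute_rates(beh)
  expect_equal(r$correct_rate, mean(beh$category == "no-reward"))
})

test_that("a stale policy on a reversed day starts below chance", {
  task <- task_spec()
  old_map <- task$category_map
  new_map <- setNames(ifelse(old_map == "reward", "no-reward", "reward"),
                      names(old_map))
  task_rev <- task_spec(category_map = new_map)
  tr <- generate_trial_sequence(task_rev, 100, seed = 8)
  beh <- generate_behavior(tr, agent_params(), seed = 9,
                           perceived_map = old_map)
  expect_lt(compute_rates(beh)$correct_rate, 0.5)
})

test_that("zero-noise non-responsive populations are constant at baseline", {
  task <- task_spec()
  tr <- generate_behavior(generate_trial_sequence(task, 6, seed = 1),
                          agent_params(), seed = 2)
  truth <- ground_truth(0, 0, 0, n_none = 3)
  quiet <- noise_spec(baseline = 50, baseline_sd = 0, drift_amplitude = 0,
                      white_sd = 0, bg_event_rate = 0)
  sess <- generate_population(tr, truth, quiet, seed = 3, task = task)
  expect_true(all(sess$F == 50))
})

test_that("planted reward neurons respond more in Go than NoGo trials", {
  task <- task_spec()
  tr <- generate_behavior(generate_trial_sequence(task, 40, seed = 4),
                          agent_params(), seed = 5)
  truth <- ground_truth(n_reward = 1, n_noreward = 0, n_identity = 0,
                        n_none = 0, amplitude = 3, event_rate = 4)
  sess <- generate_population(tr, truth, noise_spec(), seed = 6,
                              task = task)
  ep <- sess$epochs
  stim_f <- ep[["open_complete"]]:(ep[["response"]] - 1)
  m_go <- mean(sess$F[1, stim_f, tr$category == "reward"])
  m_nogo <- mean(sess$F[1, stim_f, tr$category == "no-reward"])
  expect_gt(m_go, m_nogo)
})

test_that("population generation is deterministic per seed", {
  task <- task_spec()
  tr <- generate_behavior(generate_trial_sequence(task, 8, seed = 1),
                          agent_params(), seed = 2)
  truth <- ground_truth(1, 1, 1, 2)
  a <- generate_population(tr, truth, noise_spec(), seed = 11, task = task)
  b <- generate_population(tr, truth, noise_spec(), seed = 11, task = task)
  expect_identical(a$F, b$F)
})

test_that("reversal preserves trial-type tuning and stimulus tuning correctly", {
  task <- task_spec()
  truth <- ground_truth(n_reward = 2, n_noreward = 0, n_identity = 2,
                        n_none = 2, amplitude = 3, event_rate = 4,
                        stimuli = task$stimuli)
  md <- generate_multiday(task, truth, n_days = 2, seed = 13,
                          n_trials = 40)
  s1 <- md$sessions[[1]]; s2 <- md$sessions[[2]]
  expect_false(identical(s1$category_map, s2$category_map))
  ep <- s1$epochs
  stim_f <- ep[["open_complete"]]:(ep[["response"]] - 1)
  mod <- function(sess, local_idx, by = "category") {
    key <- sess$trials[[by]]
    ref <- if (by == "category") "reward" else sess$task$stimuli[1]
    mean(sess$F[local_idx, stim_f, key == ref]) -
      mean(sess$F[local_idx, stim_f, key != ref])
  }
  links <- regmap_links(md$regmap, 1, 2)
  for (g in which(md$sessions[[1]]$truth$class == "reward")) {
    gid <- s1$truth$global_id[g]
    l2 <- links$index_j[links$neuron == gid]
    # Go-epoch modulation present on both days despite the stimulus flip
    expect_gt(mod(s1, g), 0)
    expect_gt(mod(s2, l2), 0)
  }
  for (g in which(startsWith(s1$truth$class, "identity:"))) {
    gid <- s1$truth$global_id[g]
    stim <- sub("identity:", "", s1$truth$class[g])
    l2 <- links$index_j[links$neuron == gid]
    full_f <- ep[["open_complete"]]:(ep[["close"]] - 1)
    sel <- function(sess, li) {
      mean(sess$F[li, full_f, sess$trials$stimulus == stim]) -
        mean(sess$F[li, full_f, sess$trials$stimulus != stim])
    }
    expect_gt(sel(s1, g), 0)
    expect_gt(sel(s2, l2), 0)
  }
})

test_that("registration links are one-to-one and stability flags propagate", {
  task <- task_spec()
  truth <- ground_truth(2, 1, 2, 3, stable = c(TRUE, FALSE))
  md <- generate_multiday(task, truth, n_days = 3, seed = 17,
                          n_trials = 20)
  links12 <- regmap_links(md$regmap, 1, 2)
  links13 <- regmap_links(md$regmap, 1, 3)
  expect_equal(nrow(links12), nrow(truth))
  expect_equal(sort(links12$index_j), seq_len(nrow(truth)))
  expect_equal(sort(links13$index_j), seq_len(nrow(truth)))
  expect_equal(links12$stable, truth$stable[links12$neuron])
  # stable neurons keep their class across days, in the regmap record
  rm1 <- md$regmap[md$regmap$day == 1, ]
  rm3 <- md$regmap[md$regmap$day == 3, ]
  stable_ids <- rm1$neuron[rm1$stable]
  expect_equal(rm3$class[match(stable_ids, rm3$neuron)],
               rm1$class[match(stable_ids, rm1$neuron)])
})
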