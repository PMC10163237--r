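test_that("d-prime matches hand evaluation and its symmetries", {
  expect_equal(dprime(c(1, 2, 3), c(0, 1, 2)), 1.0)
  expect_equal(dprime(c(4, 4, 4, 5), c(4, 4, 4, 5)), 0)
  x <- rnorm(20); y <- rnorm(20, 1)
  expect_equal(dprime(x, y), -dprime(y, x))
  expect_error(dprime(1, c(1, 2)), "at least 2")
  d0 <- dprime(c(1, 1, 1), c(2, 2, 2))
  expect_true(is.na(d0))
  expect_match(attr(d0, "diagnostic"), "zero variance")
  # population-sd variant differs in the documented direction
  expect_gt(abs(dprime(c(1, 2, 3), c(0, 1, 2), sample_sd = FALSE)),
            abs(dprime(c(1, 2, 3), c(0, 1, 2))))
})

test_that("d-prime equals a naive two-pass oracle on random fixtures", {
  set.seed(31)
  for (i in 1:100) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    x1 <- rnorm(n1, sd = runif(1, 0.1, 5))
    x2 <- rnorm(n2, mean = runif(1, -2, 2))
    expect_equal(dprime(x1, x2), oracle_dprime(x1, x2),
                 tolerance = 1e-12)
  }
})

test_that("planted activated and inhibited neurons are classified correctly", {
  task <- task_spec()
  tr <- generate_behavior(generate_trial_sequence(task, 120, seed = 1),
                          agent_params(), seed = 2)
  truth_act <- ground_truth(n_reward = 3, n_noreward = 0, n_identity = 0,
                            n_none = 3, amplitude = 2, event_rate = 4)
  sess <- generate_population(tr, truth_act, noise_spec(), seed = 3,
                              task = task)
  prof <- classify_response(preprocess_session(sess), "reward",
                            restrict = "all")
  expect_true(all(prof$code[1:3] == "activated"))
  expect_true(all(prof$code[4:6] == "none"))
  # inhibited: sparse tonic activity fully suppressed in the preferred
  # epoch (a dense tonic rate would contaminate the pre-opening threshold)
  truth_inh <- ground_truth(n_reward = 3, n_noreward = 0, n_identity = 0,
                            n_none = 0, amplitude = 2, event_rate = 1.5,
                            prop_inhibited = 1, seed = 9)
  sess2 <- generate_population(tr, truth_inh,
                               noise_spec(tonic_rate = 1.5), seed = 4,
                               task = task)
  prof2 <- classify_response(preprocess_session(sess2), "reward",
                             restrict = "all")
  expect_true(all(prof2$code == "inhibited"))
})

test_that("all-zero event traces give p = 1 and code none", {
  task <- task_spec()
  tr <- generate_behavior(generate_trial_sequence(task, 20, seed = 5),
                          agent_params(), seed = 6)
  ev <- preprocess_session(generate_population(
    tr, ground_truth(0, 0, 0, 2),
    noise_spec(bg_event_rate = 0, drift_amplitude = 0, white_sd = 0.5),
    seed = 7, task = task
  ))
  prof <- classify_response(ev, "reward", restrict = "all")
  ok <- rowSums(ev$events[, , , drop = FALSE]) == 0
  expect_true(all(prof$code[ok] == "none"))
  expect_true(all(prof$p_value[ok] == 1))
})

test_that("response scores sum the two trial-type codes", {
  expect_equal(response_score(c("activated", "inhibited", "none")),
               c(1L, -1L, 0L))
  # activated in Go only -> 1; in both -> 2; inhibited in both -> -2
  expect_equal(response_score("activated") + response_score("none"), 1L)
  expect_equal(response_score("activated") + response_score("activated"), 2L)
  expect_equal(response_score("inhibited") + response_score("inhibited"),
               -2L)
})

test_that("the permutation test is deterministic, powerful and sign-correct", {
  set.seed(41)
  x <- c(rnorm(100, 2), rnorm(100, 0)) # planted d' of about 2
  labels <- factor(rep(c("go", "nogo"), each = 100),
                   levels = c("go", "nogo"))
  a <- permutation_test(x, labels, n_shuffles = 1000, seed = 5)
  b <- permutation_test(x, labels, n_shuffles = 1000, seed = 5)
  expect_identical(a$p_perm, b$p_perm)
  expect_identical(a$null, b$null)
  expect_true(a$significant)
  expect_equal(a$label, "go")
  # swapped labels flip the preference
  sw <- permutation_test(x, factor(rep(c("nogo", "go"), each = 100),
                                   levels = c("go", "nogo")),
                         n_shuffles = 1000, seed = 5)
  expect_equal(sw$label, "nogo")
})

test_that("a degenerate permutation null is never significant", {
  x <- rep(c(0, 1), 10)
  labels <- rep(c("a", "b"), 10)
  # constant amplitudes per label position but identical null everywhere
  res <- permutation_test(rep(1, 20), labels, n_shuffles = 50, seed = 1)
  expect_false(res$significant)
})

test_that("trial-type selectivity recovers planted Go and NoGo preferences", {
  task <- task_spec()
  truth <- ground_truth(n_reward = 4, n_noreward = 4, n_identity = 0,
                        n_none = 8, amplitude = 2, event_rate = 3)
  sess <- generate_session(task, truth, 100, seed = 43)
  sel <- trial_type_selectivity(preprocess_session(sess),
                                n_shuffles = 500, seed = 44,
                                restrict = "all")
  expect_true(all(sel$label[1:4] == "go"))
  expect_true(all(sel$label[5:8] == "nogo"))
  expect_true(all(sel$d_prime[1:4] > 0))
  expect_true(all(sel$d_prime[5:8] < 0))
  expect_equal(sign(sel$d_prime), sign(sel$mu_go - sel$mu_nogo))
})

test_that("pointwise d-prime rises after window opening for planted neurons", {
  task <- task_spec()
  truth <- ground_truth(n_reward = 1, n_noreward = 0, n_identity = 0,
                        n_none = 0, amplitude = 3, event_rate = 5)
  sess <- generate_session(task, truth, 80, seed = 45)
  ev <- preprocess_session(sess)
  labels <- factor(ifelse(ev$trials$category == "reward", "go", "nogo"),
                   levels = c("go", "nogo"))
  pw <- pointwise_dprime(ev, labels)
  ep <- ev$epochs
  stim <- ep[["open_complete"]]:(ep[["response"]] - 1)
  pre <- 1:(ep[["open"]] - 1)
  expect_gt(mean(pw[1, stim], na.rm = TRUE),
            mean(abs(pw[1, pre]), na.rm = TRUE) + 0.5)
  # label-shuffled series fluctuates near zero
  set.seed(46)
  shuf <- pointwise_dprime(ev, sample(as.character(labels)))
  expect_lt(abs(mean(shuf[1, stim], na.rm = TRUE)), 0.5)
  # identical values in both conditions give NA
  flat <- array(1, dim = c(1, 4, 10))
  expect_true(all(is.na(pointwise_dprime(flat, rep(c("a", "b"), 5)))))
})

test_that("passive four-mouse analysis enumerates 6 pairs and detects tuning", {
  stims <- c("m1", "m2", "m3", "m4")
  task <- task_spec(stimuli = stims,
                    category_map = setNames(rep("no-reward", 4), stims))
  truth <- ground_truth(n_reward = 0, n_noreward = 0, n_identity = 2,
                        n_none = 2, stimuli = "m1", amplitude = 3,
                        event_rate = 4)
  sess <- generate_session(task, truth, 120, seed = 47)
  res <- passive_pairwise_dprime(preprocess_session(sess),
                                 n_shuffles = 300, seed = 48)
  expect_equal(length(res$pairs[[1]]), 6)
  expect_true(all(res$significant[1:2]))
  expect_gt(res$mean_abs_d_prime[1], res$mean_abs_d_prime[3])
  expect_lt(abs(res$mean_d_prime[3]), 0.5)
})
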