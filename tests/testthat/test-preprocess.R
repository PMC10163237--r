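test_that("constant traces condition to exactly zero", {
  F <- array(7.5, dim = c(2, 30, 4))
  cond <- condition_trace(F, drift_window = 31)
  expect_true(all(cond == 0))
  expect_equal(attr(cond, "offset"), c(7.5, 7.5))
})

test_that("order-3 median filtering removes impulses but keeps plateaus", {
  nf <- 40
  x <- rep(1, nf)
  x[20] <- 10 # single-frame spike
  y <- rep(1, nf)
  y[20:22] <- 10 # 3-frame plateau
  F <- array(0, dim = c(2, nf, 1))
  F[1, , 1] <- x
  F[2, , 1] <- y
  cond <- condition_trace(F, drift_window = nf)
  # after drift subtraction the flat part sits at 1 - quantile = 0
  expect_lt(max(cond[1, ]), 2) # spike removed
  expect_gt(max(cond[2, ]), 8) # plateau survives
})

test_that("conditioning matches an independent two-loop implementation", {
  set.seed(101)
  for (rep_i in 1:10) {
    nf <- sample(20:50, 1)
    nt <- sample(2:4, 1)
    w <- sample(c(5, 11, 30, 900), 1)
    F_i <- matrix(cumsum(rnorm(nf * nt, sd = 0.3)) + 10 +
                    5 * (runif(nf * nt) < 0.05), nf, nt)
    arr <- array(F_i, dim = c(1, nf, nt))
    got <- suppressWarnings(
      condition_trace(arr, median_order = 3, drift_window = w,
                      percentile = 0.05)
    )
    want <- oracle_condition(F_i, 3, w, 0.05)
    expect_equal(as.vector(got), want, tolerance = 1e-12)
  }
})

test_that("over-long drift windows are clipped with a warning", {
  F <- array(rnorm(60, 10), dim = c(1, 30, 2))
  expect_warning(condition_trace(F, drift_window = 900), "clipping")
})

test_that("the KDE-mode baseline behaves as a mode", {
  expect_equal(estimate_baseline(rep(5, 100)), 5)
  set.seed(7)
  bimodal <- c(rnorm(900, 1, 0.05), rnorm(100, 10, 0.05))
  expect_lt(abs(estimate_baseline(bimodal) - 1), 0.1)
  # positive skew from transients pulls the mean but not the mode
  skewed <- c(rnorm(1000, 2, 0.1), runif(80, 5, 20))
  f0 <- estimate_baseline(skewed)
  expect_lt(f0, mean(skewed))
  expect_lt(abs(f0 - 2), 0.3)
})

test_that("dF/F0 follows its definition and rejects bad baselines", {
  expect_equal(compute_dff(c(2, 4, 2), 2), c(0, 1, 0))
  expect_equal(compute_dff(5, 5), 0)
  expect_error(compute_dff(1, 0, neuron = 3), "neuron 3")
  # fixture arithmetic by hand
  expect_equal(compute_dff(c(1.5, 3.75), 1.5), c(0, 1.5))
})

test_that("the two-pass threshold approaches 3xIQR of the noise", {
  set.seed(11)
  nf <- 180; nt <- 200
  dff <- matrix(rnorm(nf * nt), nf, nt)
  det <- detect_events(dff, pre_open_frames = 1:36)
  # median + 3 x IQR of a standard normal is about 4.05
  expect_lt(abs(det$threshold - 3 * 1.349), 0.35)
  expect_false(det$fallback)
  # excluded trials are exactly those with an extreme pre-opening value
  pre <- dff[1:36, ]
  expect_equal(det$excluded,
               which(apply(pre, 2, function(x) any(x > det$threshold_pass1))))
})

test_that("threshold modes differ as documented on offset data", {
  set.seed(12)
  dff <- matrix(rnorm(36 * 400, mean = 10), 36, 400)
  t_med <- detect_events(dff, 1:36, mode = "median+3iqr")$threshold
  t_raw <- detect_events(dff, 1:36, mode = "3iqr")$threshold
  t_q3 <- detect_events(dff, 1:36, mode = "q3+3iqr")$threshold
  expect_lt(abs(t_med - 14.05), 0.4)
  expect_lt(abs(t_raw - 4.05), 0.4)
  expect_gt(t_q3, t_med) # Q3 lies above the median
})

test_that("event traces keep only suprathreshold dF/F0 and planted transients", {
  set.seed(13)
  dff <- matrix(rnorm(60 * 10, sd = 0.1), 60, 10)
  det <- detect_events(dff, 1:12)
  expect_true(all(det$events >= 0))
  expect_true(all((det$events > 0) == (dff > det$threshold)))
  # one strong planted transient -> exactly one contiguous event
  dff2 <- matrix(rnorm(60 * 10, sd = 0.05), 60, 10)
  dff2[30:34, 5] <- 5
  det2 <- detect_events(dff2, 1:12)
  above <- det2$events[, 5] > 0
  runs <- rle(above)
  expect_equal(sum(runs$values), 1)
  expect_equal(which(above), 30:34)
})

test_that("all-excluded pass 1 falls back to the pass-1 threshold", {
  dff <- matrix(0, 20, 4)
  dff[1, ] <- 100 # every trial has an extreme pre-opening value
  det <- detect_events(dff, 1:5)
  expect_true(det$fallback)
  expect_equal(det$threshold, det$threshold_pass1)
})

test_that("false-positive ratio reflects excursion symmetry", {
  set.seed(14)
  x <- rnorm(200000)
  r <- false_positive_ratio(x, 2.5)
  expect_lt(abs(r - 1), 0.15) # symmetric noise
  expect_true(is.na(false_positive_ratio(rep(0, 100), 1)))
  one_sided <- c(rep(0, 50), 5, 5, rep(0, 50))
  expect_equal(false_positive_ratio(one_sided, 1), 0)
})

test_that("a full preprocessed synthetic session sits in the low false-positive regime", {
  sess <- generate_session(task_spec(), ground_truth(3, 2, 0, 15), 40,
                           seed = 21)
  ev <- preprocess_session(sess)
  expect_lt(median(ev$fp_ratio, na.rm = TRUE), 0.05)
  expect_true(all(ev$f0 > 0))
  expect_true(all(ev$events >= 0))
})

test_that("preprocessing is neuron-wise: permuting neurons permutes outputs", {
  sess <- generate_session(task_spec(), ground_truth(2, 1, 0, 3), 10,
                           seed = 22)
  ev <- preprocess_session(sess)
  perm <- c(4, 1, 6, 2, 5, 3)
  sess2 <- sess
  sess2$F <- sess$F[perm, , ]
  ev2 <- preprocess_session(sess2)
  expect_equal(ev2$threshold, ev$threshold[perm])
  expect_equal(ev2$dff, ev$dff[perm, , ])
})

test_that("dF/F0 is invariant to positive rescaling of raw fluorescence", {
  task <- task_spec()
  tr <- generate_behavior(generate_trial_sequence(task, 10, seed = 1),
                          agent_params(), seed = 2)
  sess <- generate_population(tr, ground_truth(1, 0, 0, 2),
                              noise_spec(drift_amplitude = 0), seed = 23,
                              task = task)
  ev1 <- preprocess_session(sess)
  sess$F <- sess$F * 3
  ev3 <- preprocess_session(sess)
  expect_equal(ev3$dff, ev1$dff, tolerance = 1e-10)
  expect_equal(ev3$threshold, ev1$threshold, tolerance = 1e-10)
})

test_that("event traces are idempotent under re-thresholding", {
  set.seed(24)
  dff <- matrix(rnorm(50 * 6), 50, 6)
  det <- detect_events(dff, 1:10)
  again <- det$events * (det$events > det$threshold)
  expect_identical(again, det$events)
})
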