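test_that("trial balancing keeps the minimum class count and trial order", {
  labs <- c(rep("A", 60), rep("B", 40))
  idx <- balance_trials(labs, seed = 1)
  expect_equal(as.integer(table(labs[idx])), c(40L, 40L))
  expect_identical(idx, sort(idx))
  balanced <- rep(c("A", "B"), 10)
  expect_identical(balance_trials(balanced, seed = 2), 1:20)
  labs4 <- rep(c("A", "B", "C", "D"), c(100, 70, 90, 80))
  idx4 <- balance_trials(labs4, seed = 3)
  expect_true(all(table(labs4[idx4]) == 70))
  expect_error(balance_trials(rep("A", 5)), "label")
})

test_that("leave-one-out decoding is perfect on a separable fixture and blind before it", {
  set.seed(71)
  n_tr <- 24
  arr <- array(rnorm(2 * 6 * n_tr, sd = 0.01), dim = c(2, 6, n_tr))
  labels <- rep(c("go", "nogo"), n_tr / 2)
  arr[1, 4, labels == "go"] <- 5 # one perfectly separating neuron, frame 4
  dec <- decode_timecourse(arr, labels, spec = decoder_spec(seed = 1))
  expect_equal(dec$accuracy[4], 1.0)
  expect_lt(mean(dec$accuracy[1:3]), 0.75)
  expect_equal(attr(dec, "chance"), 0.5)
  expect_equal(attr(dec, "peak_accuracy"), max(dec$accuracy))
})

test_that("permuted labels decode at chance level", {
  set.seed(72)
  arr <- array(rnorm(10 * 4 * 60), dim = c(10, 4, 60))
  labels <- sample(rep(c("a", "b"), 30))
  dec <- decode_timecourse(arr, labels, spec = decoder_spec(seed = 2))
  expect_true(all(dec$accuracy > 0.2 & dec$accuracy < 0.8))
})

test_that("the fast whole-fold path agrees with the fold-loop path at scale", {
  set.seed(73)
  arr <- array(rnorm(6 * 3 * 40), dim = c(6, 3, 40))
  labels <- rep(c("a", "b"), 20)
  arr[1, 2, labels == "a"] <- arr[1, 2, labels == "a"] + 3
  slow <- decode_timecourse(arr, labels, spec = decoder_spec(seed = 1))
  fast <- decode_timecourse(arr, labels,
                            spec = decoder_spec(fold_standardize = FALSE,
                                                seed = 1))
  expect_lt(max(abs(slow$accuracy - fast$accuracy)), 0.16)
  expect_equal(which.max(slow$accuracy), which.max(fast$accuracy))
})

test_that("winner-takes-all multiclass decoding recovers disjoint ensembles", {
  set.seed(74)
  stims <- c("A", "B", "C", "D")
  n_per <- 8
  labels <- rep(stims, n_per)
  arr <- array(rnorm(4 * 4 * length(labels), sd = 0.05),
               dim = c(4, 4, length(labels)))
  for (k in 1:4) arr[k, 3:4, labels == stims[k]] <- 4 # one ensemble each
  dec <- multiclass_decode(arr, labels, spec = decoder_spec(seed = 3))
  expect_equal(attr(dec, "chance"), 0.25)
  expect_equal(dec$accuracy[3], 1.0)
  expect_equal(dec$accuracy[4], 1.0)
  # a single informative ensemble still beats chance
  arr2 <- array(rnorm(4 * 2 * length(labels), sd = 0.05),
                dim = c(4, 2, length(labels)))
  arr2[1, 2, labels == "A"] <- 4
  dec2 <- multiclass_decode(arr2, labels, spec = decoder_spec(seed = 4))
  expect_gt(dec2$accuracy[2], 0.25)
})

test_that("decision-value ties resolve to the lowest label index", {
  # all-zero features: every fold falls back deterministically
  arr <- array(0, dim = c(3, 2, 12))
  labels <- rep(c("A", "B", "C"), 4)
  dec <- multiclass_decode(arr, labels, spec = decoder_spec(seed = 5))
  expect_equal(dec$accuracy, c(1 / 3, 1 / 3)) # always predicts "A"
})

test_that("cross-day decoding with an identity map reproduces training accuracy", {
  set.seed(75)
  arr <- array(rnorm(5 * 4 * 30, sd = 0.05), dim = c(5, 4, 30))
  labels <- rep(c("a", "b"), 15)
  arr[2, 3, labels == "a"] <- 3
  cd <- crossday_decode(arr, arr, labels, labels)
  expect_equal(cd$accuracy[3], 1.0)
  expect_equal(attr(cd, "n_trials"), 30)
  expect_error(crossday_decode(arr, arr, labels, labels,
                               links = tibble::tibble(index_i = integer(),
                                                      index_j = integer())),
               "empty")
})

test_that("cross-day decoding maps neurons through the registration links", {
  set.seed(76)
  arr1 <- array(rnorm(4 * 2 * 20, sd = 0.05), dim = c(4, 2, 20))
  labels <- rep(c("a", "b"), 10)
  arr1[1, 1, labels == "a"] <- 3 # informative neuron is index 1 on day 1
  arr2 <- arr1[c(3, 4, 1, 2), , , drop = FALSE] # ...and index 3 on day 2
  links <- tibble::tibble(index_i = 1:4, index_j = c(3, 4, 1, 2))
  cd <- crossday_decode(arr1, arr2, labels, labels, links = links)
  expect_equal(cd$accuracy[1], 1.0)
  # without the permutation-aware links, transfer collapses
  cd_wrong <- crossday_decode(arr1, arr2, labels, labels)
  expect_lt(cd_wrong$accuracy[1], 1.0)
})

test_that("cluster permutation test finds a planted effect and is deterministic", {
  set.seed(77)
  arr <- array(rnorm(6 * 12 * 24), dim = c(6, 12, 24))
  labels <- rep(c("a", "b"), 12)
  arr[, 5:8, labels == "a"] <- arr[, 5:8, labels == "a"] + 2.5
  ct <- cluster_permutation_test(arr, labels, n_perm = 200, seed = 9)
  expect_gte(nrow(ct$clusters), 1)
  top <- ct$clusters[which.max(ct$clusters$score), ]
  expect_true(top$significant)
  expect_lte(top$start_frame, 6)
  expect_gte(top$end_frame, 7)
  ct2 <- cluster_permutation_test(arr, labels, n_perm = 200, seed = 9)
  expect_identical(ct$clusters, ct2$clusters)
  # pure-noise data with the same seed yields no significant cluster
  arr0 <- array(rnorm(6 * 12 * 24), dim = c(6, 12, 24))
  ct0 <- cluster_permutation_test(arr0, labels, n_perm = 200, seed = 10)
  expect_false(any(ct0$clusters$significant))
})

test_that("peak-accuracy/performance correlation handles fixtures and degenerate input", {
  r1 <- performance_decoding_correlation(c(0.6, 0.7, 0.8, 0.9),
                                         c(0.55, 0.65, 0.75, 0.85))
  expect_equal(r1$r, 1.0)
  set.seed(78)
  r0 <- performance_decoding_correlation(runif(40), runif(40))
  expect_lt(abs(r0$r), 0.35)
  rc <- performance_decoding_correlation(rep(0.8, 5), runif(5))
  expect_true(is.na(rc$r))
  expect_error(performance_decoding_correlation(1:2, 1:2), "3")
})

test_that("decoding results expose tidy and glance summaries", {
  set.seed(79)
  arr <- array(rnorm(3 * 3 * 16), dim = c(3, 3, 16))
  labels <- rep(c("a", "b"), 8)
  dec <- decode_timecourse(arr, labels, spec = decoder_spec(seed = 1))
  td <- tidy(dec)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("frame", "time_s", "accuracy"))
  gl <- glance(dec)
  expect_equal(gl$n_frames, 3)
  expect_equal(gl$peak_accuracy, max(dec$accuracy))
})
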