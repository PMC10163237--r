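#' Linear decoder specification
#'
#' @param cost Soft-margin regularization strength C of the linear SVM
#'   (default 1, the fitting routine's conventional default).
#' @param standardize Standardize features (default TRUE).
#' @param fold_standardize Compute standardization statistics on the
#'   training fold only (default TRUE, avoiding leakage). FALSE standardizes
#'   globally, which permits the much faster whole-fold cross-validation
#'   path used by [cluster_permutation_test()].
#' @param seed Seed for tie-breaking and any subsampling.
#' @return A `ca1_decoder` list.
#' @export
decoder_spec <- function(cost = 1, standardize = TRUE,
                         fold_standardize = TRUE, seed = NULL) {
  stopifnot(cost > 0)
  structure(list(cost = cost, standardize = isTRUE(standardize),
                 fold_standardize = isTRUE(fold_standardize), seed = seed),
            class = "ca1_decoder")
}

#' Down-sample trials to balanced label counts
#'
#' Randomly subsamples, without replacement, so every label retains the
#' minimum per-label trial count; trial order is preserved.
#'
#' @param trials Trial table, or a label vector.
#' @param label_field Column holding the label when `trials` is a table
#'   (default `"stimulus"`).
#' @param seed Seed; the subset is deterministic per seed.
#' @return Sorted integer vector of retained trial indices.
#' @examples
#' balance_trials(c("a", "a", "a", "b", "b"), seed = 1)
#' @export
balance_trials <- function(trials, label_field = "stimulus", seed = NULL) {
  labels <- if (is.data.frame(trials)) trials[[label_field]] else trials
  counts <- table(labels)
  if (any(counts == 0) || length(counts) < 2) {
    abort("every label must occur at least once (and >= 2 labels present).")
  }
  m <- min(counts)
  keep <- with_seed(seed, {
    unlist(lapply(names(counts), function(l) {
      idx <- which(labels == l)
      if (length(idx) == m) idx else sort(idx[sample.int(length(idx), m)])
    }))
  })
  sort(keep)
}

# features of one frame: trials x neurons matrix
frame_features <- function(pop, frame, trial_idx = NULL) {
  x <- pop[, frame, , drop = FALSE]
  x <- matrix(x, nrow = dim(pop)[1])
  if (!is.null(trial_idx)) x <- x[, trial_idx, drop = FALSE]
  t(x)
}

scale_cols <- function(x, center, sdev) {
  keep <- sdev > 0
  if (!any(keep)) return(NULL)
  sweep(sweep(x[, keep, drop = FALSE], 2, center[keep]), 2, sdev[keep], "/")
}

# leave-one-trial-out linear SVM with training-fold standardization;
# returns the predicted label per trial
loo_predict <- function(X, y, spec) {
  n <- nrow(X)
  lev <- levels(y)
  pred <- character(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    if (spec$standardize && spec$fold_standardize) {
      ctr <- colMeans(Xtr)
      sdev <- apply(Xtr, 2, sd)
      Xs <- scale_cols(Xtr, ctr, sdev)
      xt <- if (is.null(Xs)) NULL else
        scale_cols(X[i, , drop = FALSE], ctr, sdev)
    } else {
      Xs <- Xtr
      xt <- X[i, , drop = FALSE]
    }
    if (is.null(Xs)) {
      tab <- table(ytr)
      top <- names(tab)[tab == max(tab)]
      pred[i] <- if (length(top) == 1) top else
        top[sample.int(length(top), 1)]
      next
    }
    m <- e1071::svm(Xs, droplevels(ytr), kernel = "linear",
                    cost = spec$cost, scale = FALSE)
    pred[i] <- as.character(predict(m, xt))
  }
  factor(pred, levels = lev)
}

# whole-fold leave-one-out accuracy through libsvm's internal
# cross-validation (globally standardized features)
loo_accuracy_fast <- function(X, y, cost = 1) {
  sdev <- apply(X, 2, sd)
  keep <- sdev > 0
  if (!any(keep)) return(1 / nlevels(y))
  Xs <- scale(X[, keep, drop = FALSE])
  m <- e1071::svm(Xs, y, kernel = "linear", cost = cost, scale = FALSE,
                  cross = nrow(X))
  m$tot.accuracy / 100
}

#' Time-resolved binary population decoding
#'
#' At each frame an independent linear SVM is trained and tested in a
#' leave-one-trial-out procedure: the decoder is fit on the population
#' activity vector of every trial but one (features standardized with
#' training-fold statistics) and predicts the held-out trial; accuracy is
#' the proportion of correctly classified held-out trials.
#'
#' @param pop A `ca1_events` object (its event traces are the features) or
#'   a neurons x frames x trials array (e.g. dF/F0).
#' @param labels Per-trial labels, 2 levels, balanced (see
#'   [balance_trials()]).
#' @param frames Frames to decode (default: all). Decoding every third or
#'   sixth frame is common to keep run times proportionate.
#' @param spec A [decoder_spec()].
#' @param trial_idx Optional trial subset (applied to `pop` and expected to
#'   match `labels` length).
#' @return A `ca1_decoding` tibble: `frame`, `time_s` (when the task is
#'   known), `accuracy`; attributes `chance`, `peak_accuracy`, `n_trials`.
#' @export
decode_timecourse <- function(pop, labels, frames = NULL,
                              spec = decoder_spec(), trial_idx = NULL) {
  task <- if (inherits(pop, "ca1_events")) pop$task else NULL
  arr <- if (inherits(pop, "ca1_events")) pop$events else pop
  stopifnot(is.array(arr), length(dim(arr)) == 3)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) abort("binary decoding needs exactly 2 labels.")
  if (is.null(frames)) frames <- seq_len(dim(arr)[2])
  n_lab <- if (is.null(trial_idx)) dim(arr)[3] else length(trial_idx)
  if (length(labels) != n_lab) {
    abort("`labels` length must match the number of (selected) trials.")
  }
  if (min(table(labels)) < 2) abort("need >= 2 trials per label.")

  acc <- with_seed(spec$seed, {
    vapply(frames, function(f) {
      X <- frame_features(arr, f, trial_idx)
      if (spec$standardize && !spec$fold_standardize) {
        return(loo_accuracy_fast(X, labels, spec$cost))
      }
      mean(loo_predict(X, labels, spec) == labels)
    }, numeric(1))
  })
  new_decoding(frames, acc, task, chance = 0.5, n_trials = length(labels))
}

new_decoding <- function(frames, acc, task, chance, n_trials,
                         shuffle_lo = NULL, shuffle_hi = NULL) {
  out <- tibble::tibble(
    frame = frames,
    time_s = if (is.null(task)) NA_real_ else frame_times(task)[frames],
    accuracy = acc
  )
  if (!is.null(shuffle_lo)) {
    out$shuffle_lo <- shuffle_lo
    out$shuffle_hi <- shuffle_hi
  }
  class(out) <- c("ca1_decoding", class(out))
  attr(out, "chance") <- chance
  attr(out, "peak_accuracy") <- max(acc)
  attr(out, "n_trials") <- n_trials
  out
}

# one-vs-rest decision scores of a test matrix for each class
ovr_scores <- function(Xtr, ytr, Xte, cost) {
  lev <- levels(ytr)
  scores <- matrix(NA_real_, nrow(Xte), length(lev),
                   dimnames = list(NULL, lev))
  for (cl in lev) {
    yb <- factor(ifelse(ytr == cl, "pos", "rest"), levels = c("pos", "rest"))
    m <- e1071::svm(Xtr, yb, kernel = "linear", cost = cost, scale = FALSE)
    pr <- predict(m, Xte, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # libsvm orients the decision value toward the class named first in
    # the column label ("pos/rest" vs "rest/pos")
    first <- strsplit(colnames(dv)[1], "/")[[1]][1]
    scores[, cl] <- if (identical(first, "pos")) dv[, 1] else -dv[, 1]
  }
  scores
}

wta_labels <- function(scores) {
  lev <- colnames(scores)
  # winner takes all; exact ties go to the lowest label index
  lev[apply(scores, 1, which.max)]
}

#' Time-resolved multiclass (one-vs-rest) population decoding
#'
#' Four (in general, k) binary one-vs-rest linear SVMs are trained per frame
#' in the same leave-one-trial-out procedure as [decode_timecourse()]; the
#' held-out trial's predicted label is the classifier with the largest
#' decision value (winner takes all), giving a chance level of 1/k (25% for
#' four stimulus mice). Decision-value ties resolve to the lowest label
#' index.
#'
#' @inheritParams decode_timecourse
#' @param labels Per-trial labels, k >= 3 levels, balanced.
#' @return A `ca1_decoding` tibble (chance = 1/k).
#' @export
multiclass_decode <- function(pop, labels, frames = NULL,
                              spec = decoder_spec(), trial_idx = NULL) {
  task <- if (inherits(pop, "ca1_events")) pop$task else NULL
  arr <- if (inherits(pop, "ca1_events")) pop$events else pop
  labels <- droplevels(as.factor(labels))
  k <- nlevels(labels)
  if (k < 3) abort("use decode_timecourse() for 2 labels.")
  if (is.null(frames)) frames <- seq_len(dim(arr)[2])
  acc <- vapply(frames, function(f) {
    X <- frame_features(arr, f, trial_idx)
    n <- nrow(X)
    pred <- character(n)
    for (i in seq_len(n)) {
      Xtr <- X[-i, , drop = FALSE]
      ytr <- labels[-i]
      ctr <- colMeans(Xtr)
      sdev <- apply(Xtr, 2, sd)
      if (!spec$standardize) sdev <- rep(1, length(sdev))
      Xs <- scale_cols(Xtr, ctr, sdev)
      if (is.null(Xs)) {
        pred[i] <- levels(labels)[1]
        next
      }
      xt <- scale_cols(X[i, , drop = FALSE], ctr, sdev)
      sc <- ovr_scores(Xs, ytr, xt, spec$cost)
      pred[i] <- wta_labels(sc)
    }
    mean(pred == as.character(labels))
  }, numeric(1))
  new_decoding(frames, acc, task, chance = 1 / k, n_trials = length(labels))
}

#' Cross-day decoding through registered neurons
#'
#' Trains a linear SVM per frame on every trial of one session and tests it
#' on every trial of the other, using only neurons registered on both days.
#' Also reports the mean signed deviation of accuracy from chance over the
#' stimulus epoch, and (optionally) a label-shuffle accuracy band.
#'
#' @param pop_train,pop_test `ca1_events` objects or arrays of the two
#'   sessions.
#' @param labels_train,labels_test Per-trial labels (the same 2+ levels).
#' @param links Registration links (`index_i` = train-session neuron index,
#'   `index_j` = test-session index), e.g. from [regmap_links()].
#' @param frames Frames to decode (default all).
#' @param spec A [decoder_spec()]. Standardization statistics come from the
#'   training session only.
#' @param n_shuffle Number of training-label shuffles for the chance band
#'   (0 = none).
#' @param stimulus_frames Frames defining the stimulus epoch for the mean
#'   deviation (default: opening-complete to closing when the task is
#'   known, else all decoded frames).
#' @return A `ca1_decoding` tibble with (optionally) `shuffle_lo` /
#'   `shuffle_hi` columns; attribute `mean_deviation` is the mean of
#'   (accuracy - chance) over the stimulus-epoch frames.
#' @export
crossday_decode <- function(pop_train, pop_test, labels_train, labels_test,
                            links = NULL, frames = NULL,
                            spec = decoder_spec(), n_shuffle = 0,
                            stimulus_frames = NULL) {
  task <- if (inherits(pop_train, "ca1_events")) pop_train$task else NULL
  epochs <- if (inherits(pop_train, "ca1_events")) pop_train$epochs else NULL
  a_train <- if (inherits(pop_train, "ca1_events")) pop_train$events else pop_train
  a_test <- if (inherits(pop_test, "ca1_events")) pop_test$events else pop_test
  if (is.null(links)) {
    if (dim(a_train)[1] != dim(a_test)[1]) {
      abort("sessions differ in neuron count; supply `links`.")
    }
    links <- tibble::tibble(index_i = seq_len(dim(a_train)[1]),
                            index_j = seq_len(dim(a_train)[1]))
  }
  if (nrow(links) == 0) abort("empty registration link set.")
  a_train <- a_train[links$index_i, , , drop = FALSE]
  a_test <- a_test[links$index_j, , , drop = FALSE]
  lev <- sort(unique(c(as.character(labels_train),
                       as.character(labels_test))))
  ytr <- factor(as.character(labels_train), levels = lev)
  yte <- factor(as.character(labels_test), levels = lev)
  if (is.null(frames)) frames <- seq_len(dim(a_train)[2])
  chance <- 1 / length(lev)

  acc_for <- function(y) {
    vapply(frames, function(f) {
      Xtr <- frame_features(a_train, f)
      Xte <- frame_features(a_test, f)
      ctr <- colMeans(Xtr)
      sdev <- apply(Xtr, 2, sd)
      if (!spec$standardize) sdev <- rep(1, length(sdev))
      Xs <- scale_cols(Xtr, ctr, sdev)
      if (is.null(Xs)) return(chance)
      Xts <- scale_cols(Xte, ctr, sdev)
      if (length(lev) == 2) {
        m <- e1071::svm(Xs, droplevels(y), kernel = "linear",
                        cost = spec$cost, scale = FALSE)
        mean(as.character(predict(m, Xts)) == as.character(yte))
      } else {
        sc <- ovr_scores(Xs, y, Xts, spec$cost)
        mean(wta_labels(sc) == as.character(yte))
      }
    }, numeric(1))
  }

  acc <- acc_for(ytr)
  lo <- hi <- NULL
  if (n_shuffle > 0) {
    null_mat <- with_seed(spec$seed, {
      vapply(seq_len(n_shuffle), function(k) {
        acc_for(ytr[sample.int(length(ytr))])
      }, numeric(length(frames)))
    })
    null_mat <- matrix(null_mat, nrow = length(frames))
    lo <- apply(null_mat, 1, quantile, probs = 0.025)
    hi <- apply(null_mat, 1, quantile, probs = 0.975)
  }
  out <- new_decoding(frames, acc, task, chance = chance,
                      n_trials = length(yte), shuffle_lo = lo,
                      shuffle_hi = hi)
  if (is.null(stimulus_frames)) {
    stimulus_frames <- if (!is.null(epochs)) {
      intersect(frames, epochs[["open_complete"]]:(epochs[["close"]] - 1L))
    } else {
      frames
    }
  }
  in_epoch <- out$frame %in% stimulus_frames
  attr(out, "mean_deviation") <- mean(out$accuracy[in_epoch]) - chance
  out
}

#' Cluster-based permutation test of a decoding time course
#'
#' Assesses where a decoding accuracy time course differs from chance while
#' controlling for multiple comparisons across frames. For each of `n_perm`
#' permutations the trial labels are shuffled and the full leave-one-out
#' accuracy course recomputed; each frame's cluster-forming thresholds are
#' the pointwise 2.5th / 97.5th percentiles of the pooled observed and
#' permutation courses (pooling keeps observed and permuted courses
#' exchangeable, so the Monte Carlo p-values are exact under the null).
#' Contiguous suprathreshold frames form clusters scored by the summed
#' deviation from chance; a cluster's p-value is the fraction of
#' permutations whose own maximal cluster score (either direction) reaches
#' the observed score. Both observed and permuted courses run through the
#' identical fast whole-fold cross-validation decoder (globally
#' standardized features), so the comparison is exact.
#'
#' @param pop `ca1_events` or array.
#' @param labels Per-trial labels (2 levels, balanced).
#' @param frames Frames to test (default all).
#' @param n_perm Number of permutations (1000).
#' @param spec A [decoder_spec()]; only `cost` is used by the fast path.
#' @param seed Seed for the permutations.
#' @param alpha Cluster significance criterion (0.05).
#' @param threshold_prob Pointwise cluster-forming quantile (0.975).
#' @param trial_idx Optional trial subset.
#' @return A `ca1_clusters` list: `clusters` tibble (`start_frame`,
#'   `end_frame`, `direction`, `score`, `p_value`, `significant`),
#'   `accuracy` (the observed `ca1_decoding` course with shuffle band),
#'   `n_perm`.
#' @export
cluster_permutation_test <- function(pop, labels, frames = NULL,
                                     n_perm = 1000, spec = decoder_spec(),
                                     seed = NULL, alpha = 0.05,
                                     threshold_prob = 0.975,
                                     trial_idx = NULL) {
  arr <- if (inherits(pop, "ca1_events")) pop$events else pop
  task <- if (inherits(pop, "ca1_events")) pop$task else NULL
  labels <- droplevels(as.factor(labels))
  if (is.null(frames)) frames <- seq_len(dim(arr)[2])
  chance <- 1 / nlevels(labels)
  # pre-extract (globally standardized) features once per frame
  Xs <- lapply(frames, function(f) {
    X <- frame_features(arr, f, trial_idx)
    sdev <- apply(X, 2, sd)
    keep <- sdev > 0
    if (!any(keep)) return(NULL)
    scale(X[, keep, drop = FALSE])
  })
  course <- function(y) {
    vapply(seq_along(Xs), function(j) {
      if (is.null(Xs[[j]])) return(chance)
      m <- e1071::svm(Xs[[j]], y, kernel = "linear", cost = spec$cost,
                      scale = FALSE, cross = length(y))
      m$tot.accuracy / 100
    }, numeric(1))
  }
  obs <- course(labels)
  null_mat <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      course(labels[sample.int(length(labels))])
    }, numeric(length(frames)))
  })
  null_mat <- matrix(null_mat, nrow = length(frames))
  # cluster-forming thresholds from the pooled observed + permuted courses:
  # every course, observed or permuted, is compared against the same
  # thresholds, which keeps the Monte Carlo test exact under the null
  pool <- cbind(obs, null_mat)
  hi <- apply(pool, 1, quantile, probs = threshold_prob)
  lo <- apply(pool, 1, quantile, probs = 1 - threshold_prob)

  score_clusters <- function(acc) {
    find <- function(mask, dev) {
      if (!any(mask)) return(NULL)
      r <- rle(mask)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- which(r$values)
      purrr::map_dfr(keep, function(k) {
        idx <- starts[k]:ends[k]
        tibble::tibble(start = idx[1], end = idx[length(idx)],
                       score = sum(dev[idx]))
      })
    }
    up <- find(acc > hi, acc - chance)
    dn <- find(acc < lo, chance - acc)
    if (!is.null(up)) up$direction <- "above"
    if (!is.null(dn)) dn$direction <- "below"
    dplyr::bind_rows(up, dn)
  }
  null_max <- apply(null_mat, 2, function(acc) {
    cl <- score_clusters(acc)
    if (is.null(cl) || nrow(cl) == 0) 0 else max(cl$score)
  })
  obs_cl <- score_clusters(obs)
  clusters <- if (is.null(obs_cl) || nrow(obs_cl) == 0) {
    tibble::tibble(start_frame = integer(), end_frame = integer(),
                   direction = character(), score = numeric(),
                   p_value = numeric(), significant = logical())
  } else {
    tibble::tibble(
      start_frame = frames[obs_cl$start],
      end_frame = frames[obs_cl$end],
      direction = obs_cl$direction,
      score = obs_cl$score,
      p_value = (1 + vapply(obs_cl$score,
                            function(s) sum(null_max >= s), numeric(1))) /
        (n_perm + 1)
    ) |>
      dplyr::mutate(significant = .data$p_value < alpha)
  }
  acc_tbl <- new_decoding(frames, obs, task, chance = chance,
                          n_trials = length(labels), shuffle_lo = lo,
                          shuffle_hi = hi)
  structure(list(clusters = clusters, accuracy = acc_tbl, n_perm = n_perm,
                 alpha = alpha),
            class = "ca1_clusters")
}

#' @export
print.ca1_clusters <- function(x, ...) {
  cat("<ca1_clusters> ", nrow(x$clusters), " cluster(s), ",
      sum(x$clusters$significant), " significant (", x$n_perm,
      " permutations)\n", sep = "")
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

#' Correlation between peak decoding accuracy and behavioral performance
#'
#' @param peak_accuracies Per-session peak decoding accuracy (>= 3
#'   sessions).
#' @param correct_rates Per-session behavioral correct rates.
#' @return Tibble with Pearson `r`, two-sided `p_value` and `n`; `NA` when
#'   either vector has zero variance.
#' @export
performance_decoding_correlation <- function(peak_accuracies,
                                             correct_rates) {
  if (length(peak_accuracies) < 3 ||
      length(peak_accuracies) != length(correct_rates)) {
    abort("need >= 3 paired sessions.")
  }
  if (sd(peak_accuracies) == 0 || sd(correct_rates) == 0) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_,
                          n = length(peak_accuracies)))
  }
  ct <- cor.test(peak_accuracies, correct_rates, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(peak_accuracies))
}
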