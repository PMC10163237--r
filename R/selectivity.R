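#' Discriminability index between two sets of response amplitudes
#'
#' `d' = (mu1 - mu2) / sqrt((sigma1^2 + sigma2^2) / 2)` where `mu` and
#' `sigma` are the mean and standard deviation of per-trial calcium response
#' amplitudes of each trial type. Positive values mean group 1 responds more.
#'
#' @param responses_1,responses_2 Numeric per-trial amplitudes (each >= 2
#'   trials).
#' @param sample_sd Use the sample (n-1) standard deviation (default TRUE);
#'   FALSE uses the population form.
#' @return Scalar d'; `NA` with a diagnostic attribute when both groups have
#'   zero variance.
#' @examples
#' dprime(c(1, 2, 3), c(0, 1, 2)) # 1
#' @export
dprime <- function(responses_1, responses_2, sample_sd = TRUE) {
  if (length(responses_1) < 2 || length(responses_2) < 2) {
    abort("each group needs at least 2 trials.")
  }
  v <- function(x) {
    if (sample_sd) var(x) else mean((x - mean(x))^2)
  }
  denom <- sqrt((v(responses_1) + v(responses_2)) / 2)
  if (denom == 0) {
    return(structure(NA_real_, diagnostic = "zero variance in both groups"))
  }
  (mean(responses_1) - mean(responses_2)) / denom
}

#' Per-trial response amplitudes in an analysis window
#'
#' The amplitude of a trial is the mean event-trace (or dF/F0) value over
#' the window frames; `window = "open_response"` is the reward / no-reward
#' discrimination window (window opening to response-window start),
#' `"open_close"` the identity window (opening to closing), and
#' `"stimulus"` the opening-complete to response-window interval.
#'
#' @param events A `ca1_events` object.
#' @param window Window name or an integer vector of frame indices.
#' @param source `"events"` (default, thresholded trace) or `"dff"`.
#' @return Numeric matrix, neurons x trials.
#' @export
response_amplitudes <- function(events,
                                window = c("open_response", "open_close",
                                           "stimulus"),
                                source = c("events", "dff")) {
  source <- match.arg(source)
  frames <- resolve_window(events$epochs, window)
  x <- events[[source]][, frames, , drop = FALSE]
  apply(x, c(1, 3), mean)
}

resolve_window <- function(epochs, window) {
  if (is.numeric(window)) return(as.integer(window))
  window <- match.arg(window, c("open_response", "open_close", "stimulus",
                                "pre_open"))
  switch(window,
         open_response = epochs[["open"]]:(epochs[["response"]] - 1L),
         open_close = epochs[["open"]]:(epochs[["close"]] - 1L),
         stimulus = epochs[["open_complete"]]:(epochs[["response"]] - 1L),
         pre_open = 1L:(epochs[["open"]] - 1L))
}

#' Trials entering calcium analyses
#'
#' All calcium analyses default to correct trials (hits and CRs) inside the
#' session's high-performance period.
#'
#' @param trials Scored trial table.
#' @param restrict `"correct_high"` (default) or `"all"`.
#' @return Integer trial indices.
#' @export
analysis_trials <- function(trials, restrict = c("correct_high", "all")) {
  restrict <- match.arg(restrict)
  if (restrict == "all") return(seq_len(nrow(trials)))
  hp <- find_high_performance(trials)$mask
  which(hp & trials$outcome %in% c("hit", "CR"))
}

#' Classify each neuron's response to one trial type
#'
#' Compares, across trials of one type, the area under the calcium-event
#' trace in the pre-stimulus period (trial start to window opening) against
#' the stimulus period (completion of window opening to response-window
#' start) with a paired two-sided Wilcoxon signed-rank test. A neuron is
#' `activated` if p < `alpha` and the median nonzero paired difference is
#' positive, `inhibited` if negative, otherwise `none` (zero differences are
#' excluded from the direction, as the signed-rank test discards them).
#'
#' @param events A `ca1_events` object.
#' @param trial_type `"reward"` (Go) or `"no-reward"` (NoGo).
#' @param restrict Trial restriction, see [analysis_trials()].
#' @param alpha Significance criterion (0.05).
#' @return Tibble, one row per neuron: `neuron`, `trial_type`, `code`,
#'   `p_value`, `n_trials`.
#' @export
classify_response <- function(events, trial_type = c("reward", "no-reward"),
                              restrict = "correct_high", alpha = 0.05) {
  trial_type <- match.arg(trial_type)
  idx <- analysis_trials(events$trials, restrict)
  idx <- idx[events$trials$category[idx] == trial_type]
  if (length(idx) < 2) {
    abort(sprintf("fewer than 2 usable '%s' trials.", trial_type))
  }
  pre_f <- resolve_window(events$epochs, "pre_open")
  stim_f <- resolve_window(events$epochs, "stimulus")
  n_neurons <- dim(events$events)[1]
  pre_area <- apply(events$events[, pre_f, idx, drop = FALSE], c(1, 3), sum)
  stim_area <- apply(events$events[, stim_f, idx, drop = FALSE], c(1, 3), sum)
  res <- purrr::map_dfr(seq_len(n_neurons), function(i) {
    d <- stim_area[i, ] - pre_area[i, ]
    if (all(d == 0)) {
      p <- 1
    } else {
      p <- suppressWarnings(
        wilcox.test(stim_area[i, ], pre_area[i, ], paired = TRUE,
                    exact = FALSE)$p.value
      )
      if (is.na(p)) p <- 1
    }
    # direction from the nonzero paired differences (the signed-rank test
    # itself discards zero differences)
    dir <- median(d[d != 0])
    code <- if (p < alpha && dir > 0) {
      "activated"
    } else if (p < alpha && dir < 0) {
      "inhibited"
    } else {
      "none"
    }
    tibble::tibble(neuron = i, trial_type = trial_type, code = code,
                   p_value = p, n_trials = length(idx))
  })
  res
}

#' Response codes and scores for both trial types
#'
#' Runs [classify_response()] on Go (reward) and NoGo (no-reward) trials and
#' sums the codes into a response score in `[-2, 2]`: +1 per activated
#' trial type, -1 per inhibited, 0 per non-responsive. A score of 1 is a
#' neuron activated in Go but not NoGo trials; 2 is activated in both.
#'
#' @inheritParams classify_response
#' @return Tibble per neuron: `neuron`, `code_go`, `code_nogo`, `score`.
#' @export
neuron_responses <- function(events, restrict = "correct_high",
                             alpha = 0.05) {
  go <- classify_response(events, "reward", restrict, alpha)
  nogo <- classify_response(events, "no-reward", restrict, alpha)
  tibble::tibble(
    neuron = go$neuron,
    code_go = go$code,
    code_nogo = nogo$code,
    score = response_score(go$code) + response_score(nogo$code)
  )
}

#' Numeric value of a response code
#'
#' @param code Character vector of codes (`activated`, `inhibited`, `none`).
#' @return Integer vector: +1, -1, 0 respectively.
#' @export
response_score <- function(code) {
  unname(c(activated = 1L, inhibited = -1L, none = 0L)[code])
}

#' Permutation test of a d-prime value
#'
#' Builds the null distribution of d' by randomly permuting the condition
#' labels across trials `n_shuffles` times (per-condition trial counts
#' preserved). The observed d' is significant when it strictly exceeds the
#' upper `1 - 0.025 / bonferroni_m` empirical quantile of the null or falls
#' strictly below the lower `0.025 / bonferroni_m` quantile (two-sided 2.5%
#' tails; Bonferroni-corrected when several comparisons are made per
#' neuron). A degenerate null (all shuffled values identical) is never
#' significant.
#'
#' @param responses Numeric per-trial amplitudes.
#' @param labels Per-trial condition labels (2 levels).
#' @param n_shuffles Number of surrogate permutations (1000).
#' @param bonferroni_m Number of simultaneous comparisons (1 for task
#'   sessions; the number of stimulus pairs in the passive condition).
#' @param seed Seed for the shuffles.
#' @param statistic Optional function `(responses, labels) -> scalar`
#'   replacing d'; used e.g. for the passive mean-|d'| statistic, tested on
#'   the upper tail only.
#' @return List: `d_prime` (observed statistic), `p_perm`, `significant`,
#'   `label` (preferred level, or `"none"`), `null` (the null sample).
#' @export
permutation_test <- function(responses, labels, n_shuffles = 1000,
                             bonferroni_m = 1, seed = NULL,
                             statistic = NULL) {
  lev <- if (is.factor(labels)) levels(labels) else unique(as.character(labels))
  labels <- as.character(labels)
  one_sided <- !is.null(statistic)
  stat_fun <- statistic %||% function(x, l) {
    dprime(x[l == lev[1]], x[l == lev[2]])
  }
  if (!one_sided && length(lev) != 2) {
    abort("`labels` must have exactly 2 levels.")
  }
  obs <- stat_fun(responses, labels)
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(k) {
      stat_fun(responses, labels[sample.int(length(labels))])
    }, numeric(1))
  })
  if (is.na(obs) || all(is.na(null))) {
    return(list(d_prime = obs, p_perm = NA_real_, significant = FALSE,
                label = "none", null = null))
  }
  null_ok <- null[!is.na(null)]
  degenerate <- length(unique(null_ok)) == 1L
  alpha_tail <- 0.025 / bonferroni_m
  hi <- unname(quantile(null_ok, 1 - alpha_tail))
  lo <- unname(quantile(null_ok, alpha_tail))
  if (one_sided) {
    sig <- !degenerate && obs > unname(quantile(null_ok, 1 - 2 * alpha_tail))
    p <- (1 + sum(null_ok >= obs)) / (length(null_ok) + 1)
    label <- if (sig) "selective" else "none"
  } else {
    sig <- !degenerate && (obs > hi || obs < lo)
    p <- min(1, 2 * min(1 + sum(null_ok >= obs), 1 + sum(null_ok <= obs)) /
               (length(null_ok) + 1))
    label <- if (!sig) "none" else if (obs > 0) lev[1] else lev[2]
  }
  list(d_prime = obs, p_perm = p, significant = sig, label = label,
       null = null)
}

#' Trial-type (Go/NoGo) selectivity of every neuron
#'
#' Computes each neuron's d' between reward (Go) and no-reward (NoGo) trial
#' amplitudes over the opening-to-response window and tests it against a
#' label-permutation null. Positive d' means a larger Go response.
#'
#' @param events A `ca1_events` object.
#' @param n_shuffles Permutations per neuron (1000).
#' @param seed Seed; each neuron uses a child seed so results do not depend
#'   on neuron order.
#' @param restrict Trial restriction, see [analysis_trials()].
#' @param window Amplitude window (default `"open_response"`).
#' @param source `"events"` or `"dff"` amplitudes.
#' @return A `ca1_selectivity` tibble per neuron: `neuron`, `mu_go`,
#'   `mu_nogo`, `sigma_go`, `sigma_nogo`, `d_prime`, `p_perm`, `label`
#'   (`"go"`, `"nogo"`, `"none"`).
#' @examples
#' sess <- generate_session(task_spec(), ground_truth(3, 2, 0, 5), 60,
#'                          seed = 1)
#' sel <- trial_type_selectivity(preprocess_session(sess), n_shuffles = 200,
#'                               seed = 2, restrict = "all")
#' table(sel$label)
#' @export
trial_type_selectivity <- function(events, n_shuffles = 1000, seed = NULL,
                                   restrict = "correct_high",
                                   window = "open_response",
                                   source = "events") {
  idx <- analysis_trials(events$trials, restrict)
  labels <- ifelse(events$trials$category[idx] == "reward", "go", "nogo")
  if (sum(labels == "go") < 2 || sum(labels == "nogo") < 2) {
    abort("need at least 2 usable trials of each type.")
  }
  amps <- response_amplitudes(events, window, source)[, idx, drop = FALSE]
  out <- purrr::map_dfr(seq_len(nrow(amps)), function(i) {
    x <- amps[i, ]
    pt <- permutation_test(x, factor(labels, levels = c("go", "nogo")),
                           n_shuffles = n_shuffles,
                           seed = if (is.null(seed)) NULL else
                             child_seed(seed, paste0("neuron.", i)))
    tibble::tibble(
      neuron = i,
      mu_go = mean(x[labels == "go"]),
      mu_nogo = mean(x[labels == "nogo"]),
      sigma_go = sd(x[labels == "go"]),
      sigma_nogo = sd(x[labels == "nogo"]),
      d_prime = as.numeric(pt$d_prime),
      p_perm = pt$p_perm,
      label = pt$label
    )
  })
  class(out) <- c("ca1_selectivity", class(out))
  attr(out, "n_trials") <- length(idx)
  out
}

#' Frame-by-frame d-prime time course
#'
#' d' computed at each frame from the per-trial activity at that frame,
#' for every neuron. Frames where both conditions have zero variance give
#' `NA`.
#'
#' @param pop Neurons x frames x trials array (event traces or dF/F0), or a
#'   `ca1_events` object (its event traces are used).
#' @param labels Per-trial condition labels (2 levels); group 1 is the first
#'   level.
#' @param trial_idx Optional trial subset.
#' @return Numeric matrix, neurons x frames.
#' @export
pointwise_dprime <- function(pop, labels, trial_idx = NULL) {
  if (inherits(pop, "ca1_events")) pop <- pop$events
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) abort("`labels` must have exactly 2 levels.")
  if (!is.null(trial_idx)) {
    pop <- pop[, , trial_idx, drop = FALSE]
    labels <- labels[trial_idx]
  }
  g1 <- which(labels == levels(labels)[1])
  g2 <- which(labels == levels(labels)[2])
  if (length(g1) < 2 || length(g2) < 2) {
    abort("need at least 2 trials per condition.")
  }
  d <- dim(pop)
  out <- matrix(NA_real_, d[1], d[2])
  for (f in seq_len(d[2])) {
    x1 <- pop[, f, g1, drop = TRUE]
    x2 <- pop[, f, g2, drop = TRUE]
    if (d[1] == 1) {
      x1 <- matrix(x1, nrow = 1)
      x2 <- matrix(x2, nrow = 1)
    }
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- rowSums((x1 - m1)^2) / (length(g1) - 1)
    v2 <- rowSums((x2 - m2)^2) / (length(g2) - 1)
    denom <- sqrt((v1 + v2) / 2)
    out[, f] <- ifelse(denom > 0, (m1 - m2) / denom, NA_real_)
  }
  out
}

#' Pairwise stimulus discriminability in the passive four-mouse condition
#'
#' With four unrewarded stimulus mice there are 6 unordered pairs; each
#' neuron's d' is computed for every pair over the opening-to-closing
#' window and averaged. Significance uses a permutation of the stimulus
#' labels with the mean |d'| statistic, Bonferroni-corrected over the 6
#' pairs.
#'
#' @param events A `ca1_events` object whose session has 4 stimuli, none
#'   rewarded.
#' @param n_shuffles Permutations (1000).
#' @param seed Seed.
#' @param restrict Trial restriction (default `"all"`: the passive condition
#'   has no performance criterion).
#' @return Tibble per neuron: `neuron`, `mean_d_prime` (signed mean over
#'   pairs), `mean_abs_d_prime`, `p_perm`, `significant`, plus a `pairs`
#'   list-column of the 6 per-pair d' values.
#' @export
passive_pairwise_dprime <- function(events, n_shuffles = 1000, seed = NULL,
                                    restrict = "all") {
  stims <- sort(unique(events$trials$stimulus))
  if (length(stims) != 4) abort("passive analysis expects 4 stimuli.")
  idx <- analysis_trials(events$trials, restrict)
  labels <- events$trials$stimulus[idx]
  counts <- table(labels)
  if (any(counts < 2)) {
    abort("every stimulus needs at least 2 trials.")
  }
  amps <- response_amplitudes(events, "open_close")[, idx, drop = FALSE]
  pairs <- utils::combn(stims, 2, simplify = FALSE)
  mean_abs_pair_d <- function(x, l) {
    mean(vapply(pairs, function(p) {
      abs(dprime(x[l == p[1]], x[l == p[2]]))
    }, numeric(1)))
  }
  out <- purrr::map_dfr(seq_len(nrow(amps)), function(i) {
    x <- amps[i, ]
    pair_d <- vapply(pairs, function(p) {
      dprime(x[labels == p[1]], x[labels == p[2]])
    }, numeric(1))
    pt <- permutation_test(
      x, labels, n_shuffles = n_shuffles, bonferroni_m = length(pairs),
      seed = if (is.null(seed)) NULL else child_seed(seed, paste0("pn.", i)),
      statistic = mean_abs_pair_d
    )
    tibble::tibble(
      neuron = i,
      mean_d_prime = mean(pair_d),
      mean_abs_d_prime = mean(abs(pair_d)),
      p_perm = pt$p_perm,
      significant = pt$significant,
      pairs = list(setNames(pair_d, vapply(pairs, paste, "",
                                           collapse = ":")))
    )
  })
  out
}
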