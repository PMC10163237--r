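# Shared fixtures, built in code at test time.

two_mouse_task <- function(...) task_spec(...)

# hand-assembled trial table with explicit lick times
make_trials <- function(stimulus, lick_times, task = task_spec(),
                        day = 1L) {
  n <- length(stimulus)
  stopifnot(length(lick_times) == n)
  t_open <- task$pre_open_imaging_s
  tibble::tibble(
    trial_idx = seq_len(n),
    day = as.integer(day),
    stimulus = stimulus,
    category = unname(task$category_map[stimulus]),
    t_open = t_open,
    t_open_complete = t_open + task$opening_motion_s,
    t_response = t_open + task$grace_s,
    t_close = t_open + task$window_open_s,
    lick_times = lick_times,
    outcome = NA_character_,
    rewarded = NA
  )
}

# trial table with prescribed outcomes (licks constructed to match)
make_scored_trials <- function(outcomes, task = task_spec(), day = 1L) {
  rew_stim <- names(task$category_map)[task$category_map == "reward"][1]
  nor_stim <- names(task$category_map)[task$category_map == "no-reward"][1]
  stim <- ifelse(outcomes %in% c("hit", "miss"), rew_stim, nor_stim)
  licks <- lapply(outcomes, function(o) {
    if (o %in% c("hit", "FA")) task$pre_open_imaging_s + task$grace_s + 0.3
    else numeric(0)
  })
  score_trials(make_trials(stim, licks, task = task, day = day))
}

# minimal session wrapper around a scored trial table (near-zero F array)
make_session <- function(trials, task = task_spec(), n_neurons = 1) {
  F <- array(1, dim = c(n_neurons, task$n_frames, nrow(trials)))
  ca1_session(trials = trials, F = F, task = task)
}

# independent naive oracle: per-window rates by explicit loops
oracle_window_rates <- function(outcomes, categories, window) {
  n <- length(outcomes)
  out <- NULL
  for (s in 1:(n - window + 1)) {
    idx <- s:(s + window - 1)
    hits <- 0; crs <- 0; nr <- 0; nn <- 0
    for (i in idx) {
      if (categories[i] == "reward") {
        nr <- nr + 1
        if (outcomes[i] == "hit") hits <- hits + 1
      } else {
        nn <- nn + 1
        if (outcomes[i] == "CR") crs <- crs + 1
      }
    }
    out <- rbind(out, c(hit = if (nr) hits / nr else NA,
                        cr = if (nn) crs / nn else NA,
                        correct = (hits + crs) / window))
  }
  out
}

# independent naive oracle for condition_trace: explicit loops
oracle_condition <- function(F_i, median_order, drift_window, percentile) {
  nf <- nrow(F_i); nt <- ncol(F_i)
  half <- (median_order - 1) / 2
  sm <- F_i
  if (median_order > 1) {
    for (tr in 1:nt) {
      for (f in 1:nf) {
        if (f - half >= 1 && f + half <= nf) {
          sm[f, tr] <- median(F_i[(f - half):(f + half), tr])
        } # edges kept
      }
    }
  }
  trace <- as.vector(sm)
  L <- length(trace)
  w <- min(drift_window, L)
  hl <- ceiling((w - 1) / 2); hr <- floor((w - 1) / 2)
  out <- numeric(L)
  for (i in 1:L) {
    win <- trace[max(1, i - hl):min(L, i + hr)]
    out[i] <- trace[i] - unname(quantile(win, percentile, type = 7))
  }
  out
}

# naive two-pass d-prime oracle
oracle_dprime <- function(x1, x2) {
  m1 <- sum(x1) / length(x1)
  m2 <- sum(x2) / length(x2)
  v1 <- sum((x1 - m1)^2) / (length(x1) - 1)
  v2 <- sum((x2 - m2)^2) / (length(x2) - 1)
  (m1 - m2) / sqrt((v1 + v2) / 2)
}
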