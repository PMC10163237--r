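#' Score trial outcomes from licking in the response window
#'
#' A trial's outcome is determined solely by whether any lick falls in the
#' response window `[t_response, t_close)`: reward-category trials become
#' hits (and are rewarded) if licked there, misses otherwise; no-reward
#' trials become false alarms if licked, correct rejections otherwise.
#' Licks during the grace period have no consequence, and a lick exactly at
#' window closing does not count (half-open interval).
#'
#' @param trials Trial table with `lick_times` (list column of seconds from
#'   trial start) and epoch times.
#' @return The table with `outcome` in `hit`/`miss`/`FA`/`CR` and `rewarded`
#'   filled.
#' @examples
#' trials <- generate_trial_sequence(task_spec(), 4, seed = 1)
#' trials$lick_times <- list(3.2, numeric(0), 0.5, 2.9)
#' score_trials(trials)$outcome
#' @export
score_trials <- function(trials) {
  check_trial_epochs(trials)
  if (!"lick_times" %in% names(trials)) {
    abort("trial table lacks column(s): lick_times")
  }
  licked <- purrr::pmap_lgl(
    list(trials$lick_times, trials$t_response, trials$t_close),
    function(licks, r, cl) {
      length(licks) > 0 && any(licks >= r & licks < cl)
    }
  )
  reward <- trials$category == "reward"
  trials$outcome <- dplyr::case_when(
    reward & licked ~ "hit",
    reward & !licked ~ "miss",
    !reward & licked ~ "FA",
    TRUE ~ "CR"
  )
  trials$rewarded <- trials$outcome == "hit"
  trials
}

#' Hit, correct-rejection and correct rates
#'
#' Hit rate = hits / reward trials, CR rate = CRs / no-reward trials,
#' correct rate = (hits + CRs) / trials — overall or in sliding windows.
#'
#' @param trials Scored trial table.
#' @param window `"all"` for a single overall value, or an integer window
#'   length for rates in sliding windows.
#' @param stride Step between window starts in trials (default 1).
#' @return A tibble with one row per window (`window_start`, `window_end`)
#'   or a single row for `"all"`, and columns `n_reward`, `n_noreward`,
#'   `hit_rate`, `cr_rate`, `correct_rate`.
#' @examples
#' trials <- generate_behavior(generate_trial_sequence(task_spec(), 100,
#'                                                     seed = 1),
#'                             agent_params(), seed = 2)
#' compute_rates(trials)
#' @export
compute_rates <- function(trials, window = "all", stride = 1) {
  if (any(is.na(trials$outcome))) abort("outcomes must be set; run score_trials().")
  n <- nrow(trials)
  one <- function(idx) {
    o <- trials$outcome[idx]
    cat_ <- trials$category[idx]
    nr <- sum(cat_ == "reward")
    nn <- sum(cat_ == "no-reward")
    tibble::tibble(
      window_start = idx[1], window_end = idx[length(idx)],
      n_reward = nr, n_noreward = nn,
      hit_rate = if (nr > 0) sum(o == "hit") / nr else NA_real_,
      cr_rate = if (nn > 0) sum(o == "CR") / nn else NA_real_,
      correct_rate = sum(o %in% c("hit", "CR")) / length(idx)
    )
  }
  if (identical(window, "all")) return(one(seq_len(n)))
  window <- as.integer(window)
  if (window > n) {
    warn("window exceeds session length; returning a single overall value.")
    return(one(seq_len(n)))
  }
  starts <- seq.int(1L, n - window + 1L, by = as.integer(stride))
  purrr::map_dfr(starts, function(s) one(s:(s + window - 1L)))
}

#' High-performance periods of a session
#'
#' Hit and CR rates are computed in a sliding window of `window` trials
#' (stride 1 by default); every trial covered by at least one window with
#' both rates strictly above `threshold` belongs to the high-performance
#' period. A high-performance session is one whose period contains strictly
#' more than `min_trials` trials.
#'
#' @param trials Scored trial table.
#' @param window Sliding-window length in trials (50).
#' @param threshold Rate criterion, strict (0.8).
#' @param min_trials Session criterion on the masked trial count, strict
#'   (200).
#' @param stride Window stride in trials (default 1).
#' @return A list with `mask` (logical per trial), `n_high` (masked count),
#'   `session_high_performance` (flag) and `windows` (the per-window rate
#'   tibble).
#' @examples
#' trials <- generate_behavior(generate_trial_sequence(task_spec(), 300,
#'                                                     seed = 1),
#'                             agent_params(), seed = 2)
#' find_high_performance(trials)$session_high_performance
#' @export
find_high_performance <- function(trials, window = 50, threshold = 0.8,
                                  min_trials = 200, stride = 1) {
  if (any(is.na(trials$outcome))) abort("outcomes must be set; run score_trials().")
  n <- nrow(trials)
  mask <- rep(FALSE, n)
  wins <- NULL
  if (n >= window) {
    wins <- compute_rates(trials, window = window, stride = stride)
    good <- !is.na(wins$hit_rate) & !is.na(wins$cr_rate) &
      wins$hit_rate > threshold & wins$cr_rate > threshold
    for (i in which(good)) mask[wins$window_start[i]:wins$window_end[i]] <- TRUE
  }
  list(
    mask = mask,
    n_high = sum(mask),
    session_high_performance = sum(mask) > min_trials,
    windows = wins
  )
}

#' Per-trial response times
#'
#' Time of the first lick of each trial relative to window opening; `NA`
#' for lick-free trials.
#'
#' @param trials Trial table with `lick_times`.
#' @return Numeric vector, seconds from `t_open`.
#' @export
response_times <- function(trials) {
  check_trial_epochs(trials)
  purrr::map2_dbl(trials$lick_times, trials$t_open, function(l, o) {
    if (length(l) == 0) NA_real_ else min(l) - o
  })
}

#' Find contingency-reversed high-performance session pairs
#'
#' Returns ordered session pairs (earlier day first) whose stimulus-reward
#' category maps are exactly reversed, whose day gap is at most
#' `max_gap_days`, and which are both high-performance sessions.
#'
#' @param sessions List of [ca1_session] objects.
#' @param max_gap_days Maximal day difference (default 1: consecutive days).
#' @param require_high Require both sessions to pass the high-performance
#'   criterion (default TRUE).
#' @return Tibble with columns `i`, `j` (positions in `sessions`), `day_i`,
#'   `day_j`, `gap`.
#' @export
pair_reversed_sessions <- function(sessions, max_gap_days = 1,
                                   require_high = TRUE) {
  info <- purrr::map_dfr(seq_along(sessions), function(k) {
    s <- sessions[[k]]
    tibble::tibble(
      k = k, day = s$day,
      high = find_high_performance(s$trials)$session_high_performance
    )
  })
  maps <- purrr::map(sessions, function(s) s$category_map[sort(names(s$category_map))])
  reversed <- function(a, b) {
    identical(names(a), names(b)) &&
      all(ifelse(a == "reward", "no-reward", "reward") == b)
  }
  out <- list()
  for (a in seq_along(sessions)) {
    for (b in seq_along(sessions)) {
      if (info$day[b] <= info$day[a]) next
      if (info$day[b] - info$day[a] > max_gap_days) next
      if (!reversed(maps[[a]], maps[[b]])) next
      if (require_high && !(info$high[a] && info$high[b])) next
      out[[length(out) + 1]] <- tibble::tibble(
        i = a, j = b, day_i = info$day[a], day_j = info$day[b],
        gap = info$day[b] - info$day[a]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(i = integer(), j = integer(), day_i = integer(),
                          day_j = integer(), gap = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$day_i, .data$day_j)
}
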