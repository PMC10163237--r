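#' Generate a pseudo-random stimulus schedule
#'
#' Draws the per-trial stimulus sequence under the two presentation
#' constraints of the task: the same stimulus never appears on more than
#' three consecutive trials, and the accumulated presentation counts of any
#' two stimuli never differ by more than `max_imbalance` at any prefix of
#' the session. Each trial is drawn by rejection sampling: a stimulus is
#' picked uniformly among those that violate neither constraint.
#'
#' @param task A [task_spec()].
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @param max_run Maximal run length of one stimulus (default 3).
#' @param max_imbalance Maximal pairwise difference in accumulated counts
#'   (default 10).
#' @param day Day index stored in the table (default 1).
#' @return A trial-table tibble with columns `trial_idx`, `day`, `stimulus`,
#'   `category`, epoch times `t_open`, `t_open_complete`, `t_response`,
#'   `t_close` (seconds from trial start), an empty `lick_times` list column
#'   and unset `outcome`/`rewarded`.
#' @examples
#' trials <- generate_trial_sequence(task_spec(), n_trials = 20, seed = 1)
#' table(trials$stimulus)
#' @export
generate_trial_sequence <- function(task, n_trials, seed = NULL,
                                    max_run = 3, max_imbalance = 10,
                                    day = 1L) {
  stopifnot(inherits(task, "ca1_task"))
  if (n_trials < 1) abort("`n_trials` must be >= 1.")
  stimuli <- task$stimuli
  k <- length(stimuli)

  seq_idx <- with_seed(seed, {
    counts <- integer(k)
    run_len <- 0L
    last <- 0L
    out <- integer(n_trials)
    for (i in seq_len(n_trials)) {
      ok <- rep(TRUE, k)
      if (k > 1) {
        if (run_len >= max_run && last > 0L) ok[last] <- FALSE
        # a pick is allowed if afterwards no pairwise count gap exceeds the cap
        for (s in seq_len(k)) {
          if (ok[s] && (counts[s] + 1L - min(counts[-s])) > max_imbalance) {
            ok[s] <- FALSE
          }
        }
      }
      cand <- which(ok)
      pick <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
      out[i] <- pick
      counts[pick] <- counts[pick] + 1L
      run_len <- if (pick == last) run_len + 1L else 1L
      last <- pick
    }
    out
  })

  stim <- stimuli[seq_idx]
  t_open <- task$pre_open_imaging_s
  tibble::tibble(
    trial_idx = seq_len(n_trials),
    day = as.integer(day),
    stimulus = stim,
    category = unname(task$category_map[stim]),
    t_open = t_open,
    t_open_complete = t_open + task$opening_motion_s,
    t_response = t_open + task$grace_s,
    t_close = t_open + task$window_open_s,
    lick_times = vector("list", n_trials),
    outcome = NA_character_,
    rewarded = NA
  )
}
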