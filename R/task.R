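#' Define the Go/NoGo discrimination task timing and stimulus set
#'
#' Captures the timing of one head-fixed discrimination trial: the interaction
#' window opens at `t = 0`, takes `opening_motion_s` to open completely, a
#' grace (delay) period of `grace_s` follows during which licks have no
#' consequence, the response window then runs until the interaction window
#' closes `window_open_s` after opening. Imaging covers `pre_open_imaging_s`
#' before opening through `post_close_imaging_s` after closing at
#' `frame_rate_hz`. Defaults give 180 frames per trial at 30 frames/s.
#'
#' @param stimuli Character vector of stimulus labels (2 or 4 stimulus mice).
#' @param category_map Named character vector mapping each stimulus to
#'   `"reward"` or `"no-reward"`. Default: first half reward, rest no-reward.
#' @param grace_s Delay between window opening and response-window start, in
#'   seconds; must lie in `[0.8, 1.3]` (1.3 for most animals).
#' @param window_open_s Seconds the interaction window stays open (4 s).
#' @param opening_motion_s Seconds the window takes to open fully (~0.4 s).
#' @param iti_s Trial period in seconds (trials repeat every 12 s).
#' @param frame_rate_hz Imaging frame rate (30 frames/s).
#' @param pre_open_imaging_s Imaging lead before window opening (1.2 s).
#' @param post_close_imaging_s Imaging tail after window closing (0.8 s).
#' @return A `ca1_task` list with the fields above plus `n_frames`.
#' @examples
#' task <- task_spec()
#' task$n_frames # 180
#' @export
task_spec <- function(stimuli = c("mouseA", "mouseB"),
                      category_map = NULL,
                      grace_s = 1.3,
                      window_open_s = 4,
                      opening_motion_s = 0.4,
                      iti_s = 12,
                      frame_rate_hz = 30,
                      pre_open_imaging_s = 1.2,
                      post_close_imaging_s = 0.8) {
  stimuli <- as.character(stimuli)
  if (length(stimuli) < 1 || anyDuplicated(stimuli)) {
    abort("`stimuli` must be distinct labels.")
  }
  if (is.null(category_map)) {
    category_map <- setNames(
      rep(c("reward", "no-reward"), c(ceiling(length(stimuli) / 2),
                                      floor(length(stimuli) / 2))),
      stimuli
    )
  }
  if (!setequal(names(category_map), stimuli)) {
    abort("`category_map` must name every stimulus exactly once.")
  }
  if (!all(category_map %in% c("reward", "no-reward"))) {
    abort("categories must be 'reward' or 'no-reward'.")
  }
  if (grace_s < 0.8 || grace_s > 1.3) {
    abort("`grace_s` must lie in [0.8, 1.3].")
  }
  stopifnot(window_open_s > grace_s, opening_motion_s > 0,
            frame_rate_hz > 0, pre_open_imaging_s >= 0,
            post_close_imaging_s >= 0)
  task <- list(
    stimuli = stimuli,
    category_map = category_map[stimuli],
    grace_s = grace_s,
    window_open_s = window_open_s,
    opening_motion_s = opening_motion_s,
    iti_s = iti_s,
    frame_rate_hz = frame_rate_hz,
    pre_open_imaging_s = pre_open_imaging_s,
    post_close_imaging_s = post_close_imaging_s
  )
  task$n_frames <- round(frame_rate_hz *
                           (pre_open_imaging_s + window_open_s +
                              post_close_imaging_s))
  structure(task, class = "ca1_task")
}

#' @export
print.ca1_task <- function(x, ...) {
  cat("<ca1_task> ", length(x$stimuli), " stimuli (",
      paste0(x$stimuli, "=", substr(x$category_map, 1, 1), collapse = ", "),
      ")\n", sep = "")
  cat("  grace ", x$grace_s, " s, window ", x$window_open_s, " s, ",
      x$frame_rate_hz, " fps, ", x$n_frames, " frames/trial\n", sep = "")
  invisible(x)
}

#' Per-trial epoch frame indices for a task
#'
#' Converts the trial epoch times (window opening `O`, opening complete,
#' response-window start `R`, window closing `C`) into 1-based frame indices
#' of the per-trial imaging epoch. Frame `i` samples time
#' `(i - 1) / frame_rate_hz - pre_open_imaging_s` relative to `O`.
#'
#' @param task A [task_spec()].
#' @return Named integer vector with elements `open`, `open_complete`,
#'   `response`, `close` and attribute `n_frames`.
#' @examples
#' epoch_frames(task_spec()) # open = 37, response = 76, close = 157
#' @export
epoch_frames <- function(task) {
  stopifnot(inherits(task, "ca1_task"))
  fr <- task$frame_rate_hz
  at <- function(t_rel) as.integer(round((task$pre_open_imaging_s + t_rel) * fr)) + 1L
  out <- c(
    open = at(0),
    open_complete = at(task$opening_motion_s),
    response = at(task$grace_s),
    close = at(task$window_open_s)
  )
  attr(out, "n_frames") <- task$n_frames
  out
}

#' Frame times of a trial, relative to window opening
#'
#' @param task A [task_spec()].
#' @return Numeric vector of length `task$n_frames`, seconds relative to `O`.
#' @export
frame_times <- function(task) {
  stopifnot(inherits(task, "ca1_task"))
  (seq_len(task$n_frames) - 1) / task$frame_rate_hz - task$pre_open_imaging_s
}

#' Behavioral agent parameters for the synthetic subject
#'
#' The simulated subject acquires the Go/NoGo rule along a logistic curve in
#' trial index: its discrimination skill is
#' `plogis(learn_rate * (trial - midpoint_trial))`, interpolating the
#' probability of licking from 0.5 on both trial types (naive) to
#' `hit_asymptote` on reward trials and `fa_asymptote` on no-reward trials
#' (trained). First-lick latency after the response-window start is normal
#' with mean `latency_mean_s` and sd `latency_sd_s`, truncated at zero.
#'
#' @param learn_rate Logistic slope per trial (default 0.05).
#' @param midpoint_trial Trial index of half-maximal skill. A large negative
#'   value (default -200) yields an already-trained agent.
#' @param hit_asymptote Asymptotic lick probability on reward trials.
#' @param fa_asymptote Asymptotic lick probability on no-reward trials; must
#'   be below `hit_asymptote`.
#' @param latency_mean_s,latency_sd_s First-lick latency distribution (s).
#' @param lick_rate_hz Within-bout lick rate (Hz).
#' @param n_bout_licks Licks per response bout.
#' @return A `ca1_agent` list.
#' @export
agent_params <- function(learn_rate = 0.05,
                         midpoint_trial = -200,
                         hit_asymptote = 0.95,
                         fa_asymptote = 0.05,
                         latency_mean_s = 0.35,
                         latency_sd_s = 0.15,
                         lick_rate_hz = 7,
                         n_bout_licks = 4) {
  if (hit_asymptote <= fa_asymptote) {
    abort("`hit_asymptote` must exceed `fa_asymptote`.")
  }
  stopifnot(hit_asymptote <= 1, fa_asymptote >= 0, latency_mean_s >= 0,
            latency_sd_s >= 0, lick_rate_hz > 0, n_bout_licks >= 1)
  structure(
    list(learn_rate = learn_rate, midpoint_trial = midpoint_trial,
         hit_asymptote = hit_asymptote, fa_asymptote = fa_asymptote,
         latency_mean_s = latency_mean_s, latency_sd_s = latency_sd_s,
         lick_rate_hz = lick_rate_hz, n_bout_licks = n_bout_licks),
    class = "ca1_agent"
  )
}

#' Plant ground-truth neuron classes for the synthetic population
#'
#' Builds the per-neuron ground-truth table the generator realizes and the
#' recovery tests check against. Classes are `"reward"` (tuned to the reward
#' trial type, tracking expected outcome), `"no-reward"`, `"identity:<stim>"`
#' (tuned to one stimulus mouse regardless of its reward contingency) and
#' `"none"`. Polarity `"activated"` adds transients in the neuron's preferred
#' epoch; `"inhibited"` gives the neuron a tonic event rate that is reduced
#' in the preferred epoch (suppression is only observable against ongoing
#' activity). `stable` marks whether the neuron keeps its tuning on the next
#' day; unstable neurons are randomly re-tuned by [generate_multiday()].
#'
#' @param n_reward,n_noreward Counts of reward- / no-reward-class neurons.
#' @param n_identity Count of identity-class neurons (split evenly over
#'   `stimuli`).
#' @param n_none Count of non-responsive neurons.
#' @param stimuli Stimulus labels used for identity classes.
#' @param amplitude Peak transient amplitude, dF/F0 units of the baseline.
#' @param event_rate Added (activated) or suppressed (inhibited) event rate,
#'   events per trial in the preferred epoch.
#' @param prop_inhibited Fraction of responsive neurons given inhibited
#'   polarity.
#' @param stable Logical, recycled: does each neuron keep its tuning across
#'   days.
#' @param seed Seed for the polarity assignment.
#' @return A `ca1_truth` tibble with columns `neuron`, `class`, `polarity`,
#'   `amplitude`, `event_rate`, `stable`.
#' @examples
#' ground_truth(n_reward = 5, n_noreward = 3, n_identity = 4, n_none = 8)
#' @export
ground_truth <- function(n_reward = 20, n_noreward = 10, n_identity = 20,
                         n_none = 150, stimuli = c("mouseA", "mouseB"),
                         amplitude = 1, event_rate = 2,
                         prop_inhibited = 0, stable = TRUE, seed = NULL) {
  stopifnot(n_reward >= 0, n_noreward >= 0, n_identity >= 0, n_none >= 0)
  cls <- c(
    rep("reward", n_reward),
    rep("no-reward", n_noreward),
    if (n_identity > 0) {
      paste0("identity:", rep_len(stimuli, n_identity))
    },
    rep("none", n_none)
  )
  n <- length(cls)
  if (n == 0) abort("ground truth must contain at least one neuron.")
  responsive <- cls != "none"
  pol <- rep("none", n)
  n_resp <- sum(responsive)
  if (n_resp > 0) {
    n_inh <- round(prop_inhibited * n_resp)
    pol_resp <- rep("activated", n_resp)
    if (n_inh > 0) {
      idx <- with_seed(seed, sample.int(n_resp, n_inh))
      pol_resp[idx] <- "inhibited"
    }
    pol[responsive] <- pol_resp
  }
  out <- tibble::tibble(
    neuron = seq_len(n),
    class = cls,
    polarity = pol,
    amplitude = ifelse(responsive, amplitude, 0),
    event_rate = ifelse(responsive, event_rate, 0),
    stable = rep_len(as.logical(stable), n)
  )
  class(out) <- c("ca1_truth", class(out))
  out
}

#' Noise and transient-shape parameters for the fluorescence generator
#'
#' @param baseline Mean raw-fluorescence baseline (arbitrary units, > 0).
#' @param baseline_sd Across-neuron sd of the baseline.
#' @param drift_amplitude Peak-to-trough slow drift amplitude (same units).
#' @param drift_period_s Drift timescale in seconds.
#' @param white_sd Frame-wise Gaussian noise sd.
#' @param rise_s,decay_s Double-exponential transient time constants
#'   (GCaMP6f-like: 50 ms rise, 600 ms decay).
#' @param bg_event_rate Background transient rate, events per trial, for all
#'   neurons.
#' @param bg_amplitude Peak amplitude of background transients (dF/F0 units).
#' @param tonic_rate Tonic event rate (events per trial) given to inhibited
#'   neurons so that suppression is observable. Kept sparse: a dense tonic
#'   rate floods the pre-opening window and inflates the event threshold.
#' @param lick_artifact Add a small motor/lick transient after reward
#'   delivery on rewarded trials (robustness testing; off by default).
#' @return A `ca1_noise` list.
#' @export
noise_spec <- function(baseline = 100, baseline_sd = 10,
                       drift_amplitude = 5, drift_period_s = 120,
                       white_sd = 2, rise_s = 0.05, decay_s = 0.6,
                       bg_event_rate = 0.3, bg_amplitude = 0.5,
                       tonic_rate = 1.5, lick_artifact = FALSE) {
  if (baseline <= 0) abort("`baseline` must be positive.")
  if (rise_s <= 0 || decay_s <= 0) {
    abort("transient time constants must be positive.")
  }
  stopifnot(baseline_sd >= 0, drift_amplitude >= 0, drift_period_s > 0,
            white_sd >= 0, bg_event_rate >= 0, bg_amplitude >= 0,
            tonic_rate >= 0)
  structure(
    list(baseline = baseline, baseline_sd = baseline_sd,
         drift_amplitude = drift_amplitude, drift_period_s = drift_period_s,
         white_sd = white_sd, rise_s = rise_s, decay_s = decay_s,
         bg_event_rate = bg_event_rate, bg_amplitude = bg_amplitude,
         tonic_rate = tonic_rate, lick_artifact = isTRUE(lick_artifact)),
    class = "ca1_noise"
  )
}
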