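#' Type-I error calibration of the d-prime permutation test
#'
#' Draws `n_neurons` synthetic null neurons whose per-trial response
#' amplitudes are i.i.d. across Go and NoGo trials (labels exchangeable),
#' applies the two-sided permutation test with 2.5% tails to each, and
#' returns the percentage declared trial-type selective. Five percent is
#' expected by chance.
#'
#' @param n_neurons Number of null neurons (>= 500 recommended).
#' @param n_go,n_nogo Trials per type.
#' @param n_shuffles Permutations per neuron (1000).
#' @param seed Seed.
#' @return A tibble with `percent_significant`, `n_neurons`, and the
#'   binomial 95% confidence half-width `ci_halfwidth` (percentage points).
#' @examples
#' \donttest{calibrate_dprime_test(n_neurons = 100, seed = 1)}
#' @export
calibrate_dprime_test <- function(n_neurons = 500, n_go = 100,
                                  n_nogo = 100, n_shuffles = 1000,
                                  seed = NULL) {
  labels <- factor(rep(c("go", "nogo"), c(n_go, n_nogo)),
                   levels = c("go", "nogo"))
  sig <- with_seed(seed, {
    vapply(seq_len(n_neurons), function(i) {
      x <- rnorm(n_go + n_nogo)
      permutation_test(x, labels, n_shuffles = n_shuffles)$significant
    }, logical(1))
  })
  p <- mean(sig)
  tibble::tibble(
    percent_significant = 100 * p,
    n_neurons = n_neurons,
    ci_halfwidth = 100 * 1.96 * sqrt(0.05 * 0.95 / n_neurons)
  )
}

#' Chance-level calibration of winner-takes-all multiclass decoding
#'
#' Generates a full synthetic passive session with four stimulus mice,
#' balanced trials and a population carrying no stimulus information
#' (all neurons planted non-responsive; background transients and noise
#' only), preprocesses it, and decodes stimulus identity with the
#' one-vs-rest winner-takes-all leave-one-trial-out linear SVM over the
#' stimulus-epoch frames. Mean accuracy should sit at the 25% chance level.
#'
#' @param n_per_class Balanced trials per stimulus (60).
#' @param n_neurons Population size (20).
#' @param frame_stride Decode every `frame_stride`-th frame of the
#'   opening-to-closing epoch (12, i.e. every 0.4 s at 30 frames/s).
#' @param seed Seed.
#' @return A tibble with `mean_accuracy_pct`, `chance_pct`, `n_trials`,
#'   `n_frames`.
#' @examples
#' \donttest{calibrate_multiclass_chance(n_per_class = 12, seed = 1)}
#' @export
calibrate_multiclass_chance <- function(n_per_class = 60, n_neurons = 20,
                                        frame_stride = 12, seed = NULL) {
  stims <- c("mouseA", "mouseB", "mouseC", "mouseD")
  task <- task_spec(
    stimuli = stims,
    category_map = setNames(rep("no-reward", 4), stims)
  )
  truth <- ground_truth(n_reward = 0, n_noreward = 0, n_identity = 0,
                        n_none = n_neurons, stimuli = stims)
  # imbalance cap is 10, so ~ 4 * (n + 3) trials guarantee n of each
  n_gen <- 4 * n_per_class + 40
  trials <- generate_trial_sequence(task, n_gen,
                                    seed = child_seed(seed, "schedule"))
  trials <- generate_behavior(trials, agent_params(),
                              seed = child_seed(seed, "behavior"))
  sess <- generate_population(trials, truth, noise_spec(),
                              seed = child_seed(seed, "population"),
                              task = task)
  ev <- preprocess_session(sess)
  idx <- sort(unlist(lapply(stims, function(s) {
    head(which(trials$stimulus == s), n_per_class)
  })))
  stopifnot(length(idx) == 4 * n_per_class)
  ep <- ev$epochs
  frames <- seq(ep[["open"]], ep[["close"]] - 1L, by = frame_stride)
  dec <- multiclass_decode(ev, trials$stimulus[idx], frames = frames,
                           spec = decoder_spec(seed = child_seed(seed, "tie")),
                           trial_idx = idx)
  tibble::tibble(
    mean_accuracy_pct = 100 * mean(dec$accuracy),
    chance_pct = 25,
    n_trials = length(idx),
    n_frames = length(frames)
  )
}

#' False-positive calibration of the cluster-based permutation test
#'
#' Runs the cluster test on decoding time courses of label-free noise
#' populations and reports the fraction of sessions with at least one
#' significant cluster; at the 0.05 criterion this should not exceed 5%.
#'
#' @param n_sessions Number of simulated null sessions (100).
#' @param n_perm Permutations per session (200, a reduced inner loop).
#' @param n_trials,n_neurons,n_frames Null session dimensions.
#' @param frame_stride Decode every `frame_stride`-th frame.
#' @param seed Seed.
#' @return Tibble with `percent_sessions_significant` and `n_sessions`.
#' @examples
#' \donttest{calibrate_cluster_test(n_sessions = 5, n_perm = 50, seed = 1)}
#' @export
calibrate_cluster_test <- function(n_sessions = 100, n_perm = 200,
                                   n_trials = 20, n_neurons = 10,
                                   n_frames = 24, frame_stride = 3,
                                   seed = NULL) {
  labels <- rep(c("a", "b"), length.out = n_trials)
  frames <- seq(1L, n_frames, by = frame_stride)
  any_sig <- vapply(seq_len(n_sessions), function(s) {
    arr <- with_seed(child_seed(seed, paste0("null.", s)), {
      array(rnorm(n_neurons * n_frames * n_trials),
            dim = c(n_neurons, n_frames, n_trials))
    })
    ct <- cluster_permutation_test(arr, labels, frames = frames,
                                   n_perm = n_perm,
                                   seed = child_seed(seed, paste0("perm.", s)))
    any(ct$clusters$significant)
  }, logical(1))
  tibble::tibble(
    percent_sessions_significant = 100 * mean(any_sig),
    n_sessions = n_sessions
  )
}
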