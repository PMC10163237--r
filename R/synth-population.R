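#' GCaMP6f-like calcium transient kernel
#'
#' Double-exponential impulse response
#' `h(t) = exp(-t / decay) - exp(-t / rise)`, normalized to unit peak and
#' truncated where it falls below 1e-3 of the peak. Defaults (50 ms rise,
#' 600 ms decay) make one event span several frames at 30 frames/s.
#'
#' @param frame_rate_hz Sampling rate.
#' @param rise_s,decay_s Time constants in seconds (both > 0).
#' @return Numeric kernel sampled at the frame rate, first sample at t = 0.
#' @export
transient_kernel <- function(frame_rate_hz = 30, rise_s = 0.05,
                             decay_s = 0.6) {
  if (rise_s <= 0 || decay_s <= 0) {
    abort("transient time constants must be positive.")
  }
  t <- seq(0, decay_s * 8, by = 1 / frame_rate_hz)
  h <- exp(-t / decay_s) - exp(-t / rise_s)
  h <- h / max(h)
  h[seq_len(max(which(h > 1e-3)))]
}

#' Generate a raw-fluorescence population recording
#'
#' Builds the neurons x frames x trials raw fluorescence array for one
#' session as baseline + slow sinusoidal drift + Poisson-timed calcium
#' transients (double-exponential kernel, convolved over the concatenated
#' trace so events spill across trial boundaries as in a real recording)
#' + white Gaussian noise. Neurons planted as responsive in `truth` receive
#' extra transients (activated) or a reduced tonic event rate (inhibited) in
#' the stimulus epoch of their preferred trials: the opening-complete to
#' response-window interval for reward / no-reward classes, the
#' opening-complete to window-closing interval for identity classes.
#'
#' @param trials Scored trial table for the session.
#' @param truth A [ground_truth()] table.
#' @param noise A [noise_spec()].
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param task The [task_spec()] that produced `trials`.
#' @return A [ca1_session] object.
#' @examples
#' task <- task_spec()
#' trials <- generate_behavior(generate_trial_sequence(task, 12, seed = 1),
#'                             agent_params(), seed = 2)
#' truth <- ground_truth(n_reward = 2, n_noreward = 1, n_identity = 2,
#'                       n_none = 5)
#' sess <- generate_population(trials, truth, noise_spec(), seed = 3,
#'                             task = task)
#' dim(sess$F)
#' @export
generate_population <- function(trials, truth, noise, seed = NULL,
                                task = task_spec()) {
  stopifnot(inherits(truth, "ca1_truth"), inherits(noise, "ca1_noise"),
            inherits(task, "ca1_task"))
  check_trial_epochs(trials)
  n_neurons <- nrow(truth)
  n_trials <- nrow(trials)
  nf <- task$n_frames
  ep <- epoch_frames(task)
  fr <- task$frame_rate_hz
  L <- nf * n_trials
  kernel <- transient_kernel(fr, noise$rise_s, noise$decay_s)

  pref_frames <- function(class) {
    if (class %in% c("reward", "no-reward")) {
      ep[["open_complete"]]:(ep[["response"]] - 1L)
    } else {
      ep[["open_complete"]]:(ep[["close"]] - 1L)
    }
  }
  pref_trials <- function(class) {
    if (class == "reward") {
      which(trials$category == "reward")
    } else if (class == "no-reward") {
      which(trials$category == "no-reward")
    } else if (startsWith(class, "identity:")) {
      which(trials$stimulus == sub("^identity:", "", class))
    } else {
      integer(0)
    }
  }

  F <- with_seed(seed, {
    out <- array(0, dim = c(n_neurons, nf, n_trials))
    b <- pmax(noise$baseline + noise$baseline_sd * rnorm(n_neurons),
              0.1 * noise$baseline)
    t_global <- (seq_len(L) - 1) / fr
    for (i in seq_len(n_neurons)) {
      imp <- numeric(L)
      add_events <- function(imp, trial_set, frames, rate_per_trial, amp) {
        for (tr in trial_set) {
          n_ev <- rpois(1, rate_per_trial)
          if (n_ev > 0) {
            at <- (tr - 1L) * nf + sample(frames, n_ev, replace = TRUE)
            imp[at] <- imp[at] + amp
          }
        }
        imp
      }
      # background transients everywhere
      if (noise$bg_event_rate > 0) {
        imp <- add_events(imp, seq_len(n_trials), seq_len(nf),
                          noise$bg_event_rate, noise$bg_amplitude)
      }
      cls <- truth$class[i]
      if (truth$polarity[i] == "activated") {
        imp <- add_events(imp, pref_trials(cls), pref_frames(cls),
                          truth$event_rate[i], truth$amplitude[i])
      } else if (truth$polarity[i] == "inhibited") {
        # tonic activity everywhere, thinned in the preferred epoch
        pt <- pref_trials(cls)
        pf <- pref_frames(cls)
        supp <- min(1, truth$event_rate[i] / max(noise$tonic_rate, 1e-12))
        for (tr in seq_len(n_trials)) {
          if (tr %in% pt) {
            in_rate <- noise$tonic_rate * length(pf) / nf * (1 - supp)
            out_rate <- noise$tonic_rate * (nf - length(pf)) / nf
            imp <- add_events(imp, tr, pf, in_rate, truth$amplitude[i])
            imp <- add_events(imp, tr, setdiff(seq_len(nf), pf), out_rate,
                              truth$amplitude[i])
          } else {
            imp <- add_events(imp, tr, seq_len(nf), noise$tonic_rate,
                              truth$amplitude[i])
          }
        }
      }
      if (noise$lick_artifact && "rewarded" %in% names(trials)) {
        rew <- which(isTRUE_vec(trials$rewarded))
        if (length(rew) > 0) {
          at <- (rew - 1L) * nf + ep[["response"]]
          imp[at] <- imp[at] + 0.2
        }
      }
      trace <- b[i] * convolve_impulses(imp, kernel)
      if (noise$drift_amplitude > 0) {
        phase <- runif(1, 0, 2 * pi)
        trace <- trace + noise$drift_amplitude / 2 *
          sin(2 * pi * t_global / noise$drift_period_s + phase)
      }
      if (noise$white_sd > 0) trace <- trace + noise$white_sd * rnorm(L)
      trace <- pmax(trace + b[i], 1e-3)
      out[i, , ] <- trace
    }
    out
  })

  ca1_session(trials = trials, F = F, task = task, truth = truth)
}

# causal convolution of a sparse impulse train with a kernel, same length
# as x: the kernel is added at each event location directly, which is exact
# and much faster than an FFT at the awkward trace lengths sessions produce
convolve_impulses <- function(x, kernel) {
  out <- numeric(length(x))
  k <- length(kernel)
  for (i in which(x != 0)) {
    j <- i:min(length(x), i + k - 1L)
    out[j] <- out[j] + x[i] * kernel[seq_along(j)]
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & x
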