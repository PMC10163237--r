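#' Simulate licking behavior of a learning agent
#'
#' Fills `lick_times`, `outcome` and `rewarded` of a trial table by
#' simulating a subject whose probability of making a Go response follows
#' the logistic acquisition curve of [agent_params()]. On responded trials
#' the first lick lands in the response window at the agent's latency and is
#' followed by a short lick bout; on rewarded trials the first response-window
#' lick triggers the reward. Outcomes are then scored from the lick times by
#' [score_trials()], so labels are consistent with the licks by construction.
#'
#' @param trials Trial table from [generate_trial_sequence()].
#' @param agent An [agent_params()].
#' @param seed Integer seed.
#' @param perceived_map Optional named category map the agent believes in
#'   (stimulus -> category). Defaults to the table's true categories. Passing
#'   yesterday's map to a reversed session simulates an agent still using the
#'   old policy, whose initial correct rate falls below chance.
#' @return The trial table with `lick_times`, `outcome`, `rewarded` filled.
#' @examples
#' trials <- generate_trial_sequence(task_spec(), 50, seed = 1)
#' beh <- generate_behavior(trials, agent_params(), seed = 2)
#' table(beh$outcome)
#' @export
generate_behavior <- function(trials, agent, seed = NULL,
                              perceived_map = NULL) {
  stopifnot(inherits(agent, "ca1_agent"))
  check_trial_epochs(trials)
  n <- nrow(trials)
  perceived <- if (is.null(perceived_map)) {
    trials$category
  } else {
    if (!all(trials$stimulus %in% names(perceived_map))) {
      abort("`perceived_map` must cover every stimulus in the table.")
    }
    unname(perceived_map[trials$stimulus])
  }

  skill <- stats::plogis(agent$learn_rate *
                           (seq_len(n) - agent$midpoint_trial))
  p_go <- ifelse(perceived == "reward",
                 0.5 + (agent$hit_asymptote - 0.5) * skill,
                 0.5 - (0.5 - agent$fa_asymptote) * skill)

  trials <- with_seed(seed, {
    go <- runif(n) < p_go
    licks <- vector("list", n)
    for (i in which(go)) {
      lat <- abs(rnorm(1, agent$latency_mean_s, agent$latency_sd_s))
      first <- trials$t_response[i] + lat
      bout <- first + (seq_len(agent$n_bout_licks) - 1) / agent$lick_rate_hz
      licks[[i]] <- bout[bout < trials$t_close[i]]
    }
    trials$lick_times <- licks
    trials
  })
  score_trials(trials)
}

# shared validation of the epoch-time columns
check_trial_epochs <- function(trials) {
  need <- c("t_open", "t_open_complete", "t_response", "t_close",
            "stimulus", "category")
  missing <- setdiff(need, names(trials))
  if (length(missing) > 0) {
    abort(paste0("trial table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  with(trials, {
    if (any(!(t_open < t_open_complete & t_open_complete < t_response &
                t_response < t_close))) {
      abort("epoch times must satisfy t_open < t_open_complete < t_response < t_close.")
    }
  })
  invisible(trials)
}
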