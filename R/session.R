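#' Session record: behavior plus population fluorescence
#'
#' A `ca1_session` bundles one imaging session: the scored trial table, the
#' raw fluorescence array `F` (neurons x frames x trials), the task timing,
#' the per-trial epoch frame indices, and (for synthetic sessions) the
#' planted ground truth.
#'
#' @param trials Trial-table tibble.
#' @param F Numeric array, neurons x frames x trials.
#' @param task A [task_spec()].
#' @param truth Optional [ground_truth()] table (synthetic sessions only).
#' @param day Day index; defaults to the table's `day`.
#' @return A `ca1_session` list with elements `trials`, `F`, `task`,
#'   `epochs`, `day`, `category_map`, `truth`.
#' @export
ca1_session <- function(trials, F, task, truth = NULL, day = NULL) {
  stopifnot(inherits(task, "ca1_task"), is.array(F), length(dim(F)) == 3)
  check_trial_epochs(trials)
  if (dim(F)[3] != nrow(trials)) {
    abort("third dimension of `F` must equal the number of trials.")
  }
  if (dim(F)[2] != task$n_frames) {
    abort(sprintf("`F` has %d frames per trial but the task specifies %d.",
                  dim(F)[2], task$n_frames))
  }
  structure(
    list(
      trials = trials,
      F = F,
      task = task,
      epochs = epoch_frames(task),
      day = as.integer(day %||% trials$day[1]),
      category_map = task$category_map,
      truth = truth
    ),
    class = "ca1_session"
  )
}

#' @export
print.ca1_session <- function(x, ...) {
  d <- dim(x$F)
  cat("<ca1_session> day ", x$day, ": ", d[1], " neurons x ", d[2],
      " frames x ", d[3], " trials\n", sep = "")
  if (!all(is.na(x$trials$outcome))) {
    tab <- table(x$trials$outcome)
    cat("  outcomes: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Generate one complete synthetic session
#'
#' Convenience wrapper chaining [generate_trial_sequence()],
#' [generate_behavior()] and [generate_population()], with per-stage child
#' seeds split from `seed` via [child_seed()].
#'
#' @param task A [task_spec()].
#' @param truth A [ground_truth()] table.
#' @param n_trials Number of trials.
#' @param seed Global seed for the session.
#' @param agent An [agent_params()].
#' @param noise A [noise_spec()].
#' @param day Day index.
#' @param perceived_map Optional stale category map for the agent (see
#'   [generate_behavior()]).
#' @return A [ca1_session].
#' @export
generate_session <- function(task, truth, n_trials, seed,
                             agent = agent_params(), noise = noise_spec(),
                             day = 1L, perceived_map = NULL) {
  trials <- generate_trial_sequence(task, n_trials,
                                    seed = child_seed(seed, "schedule"),
                                    day = day)
  trials <- generate_behavior(trials, agent,
                              seed = child_seed(seed, "behavior"),
                              perceived_map = perceived_map)
  generate_population(trials, truth, noise,
                      seed = child_seed(seed, "population"), task = task)
}
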