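#' Generate a multi-day series of sessions with contingency reversals
#'
#' Simulates `n_days` consecutive sessions of the same imaged population.
#' Reward / no-reward class neurons are tuned to the *trial type*, so when
#' the stimulus-reward contingency reverses between days their preferred
#' stimulus flips while their Go/NoGo-epoch modulation is preserved;
#' identity-class neurons stay tuned to their stimulus mouse regardless of
#' its contingency. Neurons planted with `stable = FALSE` are randomly
#' re-tuned (new class, possibly none) on each subsequent day, implementing
#' representational drift. Each day's neurons appear in a day-specific local
#' order; the returned registration map links local indices across days the
#' way cross-day cell registration would.
#'
#' @param task A [task_spec()]; its `category_map` is overridden per day by
#'   `reversal_schedule`.
#' @param truth Day-1 [ground_truth()] table.
#' @param n_days Number of days (>= 2).
#' @param reversal_schedule List of length `n_days` of named category maps
#'   (stimulus -> category), one per day. Default: daily reversal of the
#'   task's map.
#' @param seed Global seed.
#' @param n_trials Trials per day (recycled).
#' @param agent,noise Agent and noise parameters shared across days.
#' @return A list with elements `sessions` (list of [ca1_session], one per
#'   day, each carrying its day's ground truth in local neuron order) and
#'   `regmap` (a `ca1_regmap` tibble: `neuron` global id, `day`, `index`
#'   local id, `class` that day, `stable` planted stability flag).
#' @examples
#' truth <- ground_truth(n_reward = 2, n_noreward = 1, n_identity = 2,
#'                       n_none = 3)
#' md <- generate_multiday(task_spec(), truth, n_days = 2, seed = 1,
#'                         n_trials = 12)
#' md$sessions[[2]]$category_map
#' @export
generate_multiday <- function(task, truth, n_days, reversal_schedule = NULL,
                              seed = NULL, n_trials = 300,
                              agent = agent_params(), noise = noise_spec()) {
  stopifnot(inherits(task, "ca1_task"), inherits(truth, "ca1_truth"))
  if (n_days < 2) abort("`n_days` must be >= 2.")
  if (is.null(reversal_schedule)) {
    flip <- function(m) setNames(
      ifelse(m == "reward", "no-reward", "reward"), names(m))
    reversal_schedule <- vector("list", n_days)
    reversal_schedule[[1]] <- task$category_map
    for (d in seq_len(n_days)[-1]) {
      reversal_schedule[[d]] <- flip(reversal_schedule[[d - 1]])
    }
  }
  if (length(reversal_schedule) != n_days) {
    abort("`reversal_schedule` must have one category map per day.")
  }
  n_trials <- rep_len(n_trials, n_days)
  n_neurons <- nrow(truth)
  classes_pool <- c("reward", "no-reward",
                    paste0("identity:", task$stimuli), "none")

  sessions <- vector("list", n_days)
  reg <- vector("list", n_days)
  truth_d <- truth
  for (d in seq_len(n_days)) {
    if (d > 1) {
      # drift: unstable neurons are re-tuned with a new random class
      drifters <- which(!truth_d$stable)
      if (length(drifters) > 0) {
        new_cls <- with_seed(child_seed(seed, paste0("drift.", d)), {
          sample(classes_pool, length(drifters), replace = TRUE)
        })
        truth_d$class[drifters] <- new_cls
        truth_d$polarity[drifters] <- ifelse(new_cls == "none", "none",
                                             "activated")
        amp <- truth$amplitude[truth$amplitude > 0]
        er <- truth$event_rate[truth$event_rate > 0]
        truth_d$amplitude[drifters] <-
          ifelse(new_cls == "none", 0,
                 if (length(amp)) max(amp) else 1)
        truth_d$event_rate[drifters] <-
          ifelse(new_cls == "none", 0,
                 if (length(er)) max(er) else 2)
      }
    }
    task_d <- task
    m <- reversal_schedule[[d]]
    if (!setequal(names(m), task$stimuli)) {
      abort("each reversal_schedule map must cover every stimulus.")
    }
    task_d$category_map <- m[task$stimuli]
    sess <- generate_session(task_d, truth_d, n_trials[d],
                             seed = child_seed(seed, paste0("day.", d)),
                             agent = agent, noise = noise, day = d)
    # day-specific local ordering (identity on day 1)
    perm <- if (d == 1) seq_len(n_neurons) else {
      with_seed(child_seed(seed, paste0("perm.", d)),
                sample.int(n_neurons))
    }
    # local index of global neuron g is match(g, perm)
    local_of <- match(seq_len(n_neurons), perm)
    sess$F <- sess$F[perm, , , drop = FALSE]
    sess$truth <- truth_d[perm, ]
    sess$truth$neuron <- seq_len(n_neurons)
    sess$truth$global_id <- perm
    sessions[[d]] <- sess
    reg[[d]] <- tibble::tibble(
      neuron = seq_len(n_neurons),
      day = d,
      index = local_of,
      class = truth_d$class,
      stable = truth_d$stable
    )
  }
  regmap <- dplyr::bind_rows(reg)
  class(regmap) <- c("ca1_regmap", class(regmap))
  list(sessions = sessions, regmap = regmap)
}

#' Cross-day neuron links from a registration map
#'
#' @param regmap A `ca1_regmap` tibble (see [generate_multiday()]) or any
#'   tibble with columns `neuron`, `day`, `index`.
#' @param day_i,day_j The two days to link.
#' @return Tibble with one row per registered neuron: `neuron` (global id),
#'   `index_i`, `index_j` (local indices on the two days) and, when present,
#'   the planted `stable` flag.
#' @export
regmap_links <- function(regmap, day_i, day_j) {
  need <- c("neuron", "day", "index")
  if (!all(need %in% names(regmap))) {
    abort("`regmap` must have columns neuron, day, index.")
  }
  a <- dplyr::filter(regmap, .data$day == day_i)
  b <- dplyr::filter(regmap, .data$day == day_j)
  out <- dplyr::inner_join(
    dplyr::select(a, "neuron", index_i = "index",
                  dplyr::any_of("stable")),
    dplyr::select(b, "neuron", index_j = "index"),
    by = "neuron"
  )
  if (anyDuplicated(out$index_i) || anyDuplicated(out$index_j)) {
    abort("registration links must be one-to-one per day pair.")
  }
  out
}
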