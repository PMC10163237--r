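#' Tidy a decoding time course
#'
#' @param x A `ca1_decoding`.
#' @param ... Unused.
#' @return A plain tibble with `frame`, `time_s`, `accuracy` and, when
#'   present, the shuffle band columns.
#' @export
tidy.ca1_decoding <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a decoding time course
#'
#' @param x A `ca1_decoding`.
#' @param ... Unused.
#' @return Tibble with `peak_accuracy`, `mean_accuracy`, `chance`,
#'   `n_trials`, `n_frames` and, for cross-day results, `mean_deviation`.
#' @export
glance.ca1_decoding <- function(x, ...) {
  out <- tibble::tibble(
    peak_accuracy = attr(x, "peak_accuracy"),
    mean_accuracy = mean(x$accuracy),
    chance = attr(x, "chance"),
    n_trials = attr(x, "n_trials"),
    n_frames = nrow(x)
  )
  if (!is.null(attr(x, "mean_deviation"))) {
    out$mean_deviation <- attr(x, "mean_deviation")
  }
  out
}

#' Tidy per-neuron selectivity results
#'
#' @param x A `ca1_selectivity`.
#' @param ... Unused.
#' @return The underlying per-neuron tibble.
#' @export
tidy.ca1_selectivity <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' Population summary of selectivity results
#'
#' @param x A `ca1_selectivity`.
#' @param ... Unused.
#' @return Tibble with neuron counts, the fraction selective and the per-
#'   label proportions.
#' @export
glance.ca1_selectivity <- function(x, ...) {
  tibble::tibble(
    n_neurons = nrow(x),
    n_trials = attr(x, "n_trials") %||% NA_integer_,
    prop_selective = mean(x$label != "none"),
    prop_go = mean(x$label == "go"),
    prop_nogo = mean(x$label == "nogo")
  )
}

#' Tidy a reversal classification
#'
#' @param x A `ca1_reversal`.
#' @param ... Unused.
#' @return The per-neuron classification tibble.
#' @export
tidy.ca1_reversal <- function(x, ...) x$classification

#' Summary of a reversal classification
#'
#' @param x A `ca1_reversal`.
#' @param ... Unused.
#' @return One-row tibble with linked-neuron counts and per-class
#'   proportions.
#' @export
glance.ca1_reversal <- function(x, ...) {
  cl <- x$classification$class
  tibble::tibble(
    n_linked = length(cl),
    n_unlinked = x$n_unlinked,
    prop_reward = mean(cl == "reward-selective"),
    prop_noreward = mean(cl == "no-reward-selective"),
    prop_mouse = mean(cl == "mouse-selective"),
    prop_none = mean(cl == "none")
  )
}

#' Tidy contingency planned comparisons
#'
#' @param x A `ca1_contingency`.
#' @param ... Unused.
#' @return The planned-comparison tibble (one row per planned cell).
#' @export
tidy.ca1_contingency <- function(x, ...) x$planned

#' One-row summary of the contingency test
#'
#' @param x A `ca1_contingency`.
#' @param ... Unused.
#' @return Tibble with `statistic`, `df`, `p_value`, `n`.
#' @export
glance.ca1_contingency <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n = sum(x$table))
}

#' Tidy significance clusters
#'
#' @param x A `ca1_clusters`.
#' @param ... Unused.
#' @return The cluster tibble.
#' @export
tidy.ca1_clusters <- function(x, ...) x$clusters
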