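#' Plot a decoding accuracy time course
#'
#' Accuracy versus time with the chance level and, when available, the
#' label-shuffle band.
#'
#' @param object A `ca1_decoding`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ca1_decoding <- function(object, ...) {
  df <- tidy(object)
  xvar <- if (all(is.na(df$time_s))) "frame" else "time_s"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]]))
  if ("shuffle_lo" %in% names(df)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$shuffle_lo, ymax = .data$shuffle_hi),
      fill = "grey80"
    )
  }
  p +
    ggplot2::geom_hline(yintercept = attr(object, "chance"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$accuracy),
                       colour = "#2c7fb8") +
    ggplot2::labs(
      x = if (xvar == "time_s") "time from window opening (s)" else "frame",
      y = "decoding accuracy"
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot cluster-test results over the accuracy course
#'
#' @param object A `ca1_clusters`.
#' @param ... Unused.
#' @return A ggplot with significant clusters shaded.
#' @export
autoplot.ca1_clusters <- function(object, ...) {
  p <- autoplot(object$accuracy)
  sig <- dplyr::filter(object$clusters, .data$significant)
  if (nrow(sig) > 0) {
    acc <- object$accuracy
    f2t <- function(fr) {
      if (all(is.na(acc$time_s))) fr else
        acc$time_s[match(fr, acc$frame)]
    }
    p <- p + ggplot2::annotate(
      "rect", xmin = f2t(sig$start_frame), xmax = f2t(sig$end_frame),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "#d95f02"
    )
  }
  p
}

#' Plot per-neuron d-prime against permutation significance
#'
#' @param object A `ca1_selectivity`.
#' @param ... Unused.
#' @return A ggplot (volcano-style; selective neurons colored by
#'   preference).
#' @export
autoplot.ca1_selectivity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d_prime,
                                   y = -log10(pmax(.data$p_perm, 1e-4)),
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(go = "#1b9e77", nogo = "#7570b3", none = "grey60")
    ) +
    ggplot2::labs(x = "d' (Go - NoGo)", y = "-log10 permutation p",
                  colour = "preference") +
    ggplot2::theme_minimal()
}

#' Sliding-window behavioral performance of a session
#'
#' Hit, CR and correct rates in sliding windows, with the high-performance
#' criterion marked.
#'
#' @param trials Scored trial table.
#' @param window Window length (50).
#' @param threshold Criterion rate (0.8).
#' @return A ggplot.
#' @export
plot_performance <- function(trials, window = 50, threshold = 0.8) {
  w <- compute_rates(trials, window = window)
  df <- tidyr::pivot_longer(
    dplyr::select(w, "window_start", "hit_rate", "cr_rate", "correct_rate"),
    -"window_start", names_to = "rate", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_start,
                                   y = .data$value,
                                   colour = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "window start (trial)", y = "rate", colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
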