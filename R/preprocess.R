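#' Median-filter and drift-correct raw fluorescence traces
#'
#' For each neuron, every trial's raw trace is smoothed with a running
#' median of order `median_order` (edge samples kept unfiltered), the trials
#' are concatenated in trial order into a single trace, and slow drift is
#' removed by subtracting the running `percentile` quantile within a
#' centered sliding window of `drift_window` frames (window truncated at the
#' trace edges).
#'
#' @param record A [ca1_session] or a neurons x frames x trials array.
#' @param median_order Odd median-filter order (default 3).
#' @param drift_window Sliding-window length in frames (default 900); values
#'   longer than the trace are clipped with a warning.
#' @param percentile Quantile subtracted within the window (default 0.05).
#' @return Numeric matrix, neurons x (frames * trials), with attribute
#'   `offset`: each neuron's global `percentile` quantile of the
#'   median-filtered trace, used to restore a positive baseline when drift
#'   correction drives it to zero (see [preprocess_session()]).
#' @export
condition_trace <- function(record, median_order = 3, drift_window = 900,
                            percentile = 0.05) {
  F <- if (inherits(record, "ca1_session")) record$F else record
  stopifnot(is.array(F), length(dim(F)) == 3)
  if (median_order %% 2 != 1 || median_order < 1) {
    abort("`median_order` must be odd and >= 1.")
  }
  d <- dim(F)
  L <- d[2] * d[3]
  if (drift_window > L) {
    warn(sprintf("drift_window (%d) exceeds trace length (%d); clipping.",
                 drift_window, L))
    drift_window <- L
  }
  out <- matrix(0, nrow = d[1], ncol = L)
  offset <- numeric(d[1])
  for (i in seq_len(d[1])) {
    m <- matrix(F[i, , ], nrow = d[2])
    if (median_order > 1) {
      m <- apply(m, 2, function(x) stats::runmed(x, median_order,
                                                 endrule = "keep"))
    }
    trace <- as.vector(m)
    offset[i] <- unname(quantile(trace, percentile))
    out[i, ] <- trace - sliding_quantile_cpp(trace, as.integer(drift_window),
                                             percentile)
  }
  attr(out, "offset") <- offset
  out
}

#' Baseline as the mode of a kernel density estimate
#'
#' `F0` is the location of the maximum of a Gaussian kernel density estimate
#' of the whole trace (Silverman's rule-of-thumb bandwidth, 512-point
#' evaluation grid spanning the data range).
#'
#' @param trace Numeric vector (one neuron's conditioned trace).
#' @return Scalar baseline estimate.
#' @examples
#' estimate_baseline(c(rnorm(900, 1, 0.05), rnorm(100, 10, 0.05))) # ~1
#' @export
estimate_baseline <- function(trace) {
  if (length(trace) == 0 || any(!is.finite(trace))) {
    abort("trace must be nonempty and finite.")
  }
  rng <- range(trace)
  if (rng[1] == rng[2]) return(rng[1])
  d <- density(trace, bw = "nrd0", n = 512, from = rng[1], to = rng[2])
  d$x[which.max(d$y)]
}

#' Relative fluorescence change
#'
#' `dF/F0 = (F - F0) / F0`, elementwise.
#'
#' @param trace Conditioned fluorescence (vector, matrix or array).
#' @param f0 Positive baseline.
#' @param neuron Optional neuron id used in the error message.
#' @return Same shape as `trace`.
#' @export
compute_dff <- function(trace, f0, neuron = NULL) {
  if (!is.finite(f0) || f0 <= 0) {
    abort(sprintf("baseline F0 = %g is not positive%s; cannot form dF/F0.",
                  f0,
                  if (is.null(neuron)) "" else paste0(" (neuron ", neuron, ")")))
  }
  (trace - f0) / f0
}

# robust threshold of the pooled pre-opening dF/F0 values
iqr_threshold <- function(x, mode = c("median+3iqr", "3iqr", "q3+3iqr")) {
  mode <- match.arg(mode)
  iqr <- unname(diff(quantile(x, c(0.25, 0.75))))
  switch(mode,
         "median+3iqr" = unname(median(x)) + 3 * iqr,
         "3iqr" = 3 * iqr,
         "q3+3iqr" = unname(quantile(x, 0.75)) + 3 * iqr)
}

#' Two-pass calcium-event thresholding of one neuron
#'
#' The event threshold is estimated from dF/F0 in the pre-window-opening
#' period: pass 1 pools those values over all trials and computes the
#' "three-interquartile" value; trials containing any pre-opening value
#' above it (putative large calcium activity) are excluded; pass 2 recomputes
#' the value from the remaining trials and uses it as the threshold `T` for
#' the entire trace. The event trace preserves dF/F0 where it exceeds `T`
#' and is zero elsewhere. Excluded trials are only removed from threshold
#' estimation, never from downstream analysis. If pass 1 excludes every
#' trial, the pass-1 value is used and flagged.
#'
#' @param dff Numeric frames x trials matrix of one neuron's dF/F0.
#' @param pre_open_frames Integer frame indices (within a trial) before the
#'   window opening.
#' @param mode Reading of "three-interquartile value": `"median+3iqr"`
#'   (default; 3 x IQR above the median, a robust z of about 4), `"3iqr"`,
#'   or `"q3+3iqr"`.
#' @return List with `threshold`, `events` (frames x trials), `excluded`
#'   (trial indices removed in pass 1), `fallback` (logical: all trials
#'   excluded), `threshold_pass1`.
#' @export
detect_events <- function(dff, pre_open_frames,
                          mode = c("median+3iqr", "3iqr", "q3+3iqr")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(dff))
  if (length(pre_open_frames) == 0) abort("empty pre-opening period.")
  pre <- dff[pre_open_frames, , drop = FALSE]
  t1 <- iqr_threshold(as.vector(pre), mode)
  bad <- which(apply(pre, 2, function(x) any(x > t1)))
  fallback <- length(bad) == ncol(dff)
  thr <- if (fallback) {
    t1
  } else if (length(bad) > 0) {
    iqr_threshold(as.vector(pre[, -bad, drop = FALSE]), mode)
  } else {
    t1
  }
  list(
    threshold = thr,
    events = dff * (dff > thr),
    excluded = bad,
    fallback = fallback,
    threshold_pass1 = t1
  )
}

#' False-positive ratio of an event threshold
#'
#' Counts contiguous excursions of dF/F0 above `+threshold` (positive
#' events) and below `-threshold` (negative events, which have no physical
#' counterpart and index noise crossings); the ratio negative/positive
#' estimates the fraction of detected events attributable to noise. `NA`
#' when no positive event exists.
#'
#' @param dff Numeric vector (one neuron's full dF/F0 trace).
#' @param threshold Event threshold from [detect_events()].
#' @return Scalar ratio, or `NA`.
#' @export
false_positive_ratio <- function(dff, threshold) {
  n_runs <- function(x) {
    r <- rle(x)
    sum(r$values)
  }
  pos <- n_runs(dff > threshold)
  neg <- n_runs(dff < -threshold)
  if (pos == 0) return(NA_real_)
  neg / pos
}

#' Full preprocessing of a session: raw F to calcium-event traces
#'
#' Runs [condition_trace()], [estimate_baseline()], [compute_dff()],
#' [detect_events()] and [false_positive_ratio()] for every neuron. If drift
#' correction leaves a neuron's baseline at or below zero, the neuron's
#' global 5th-percentile offset is added back and the baseline re-estimated;
#' such neurons are flagged in `baseline_restored`.
#'
#' @param session A [ca1_session].
#' @param median_order,drift_window,percentile See [condition_trace()].
#' @param threshold_mode See [detect_events()].
#' @return A `ca1_events` object: list with arrays `dff` and `events`
#'   (neurons x frames x trials), per-neuron vectors `f0`, `threshold`,
#'   `fp_ratio`, `baseline_restored`, `threshold_fallback`, list
#'   `excluded_trials_pass1`, and the session's `trials`, `task`, `epochs`.
#' @examples
#' sess <- generate_session(task_spec(), ground_truth(2, 1, 0, 3), 10,
#'                          seed = 1)
#' ev <- preprocess_session(sess)
#' ev$threshold
#' @export
preprocess_session <- function(session, median_order = 3, drift_window = 900,
                               percentile = 0.05,
                               threshold_mode = "median+3iqr") {
  stopifnot(inherits(session, "ca1_session"))
  cond <- condition_trace(session, median_order, drift_window, percentile)
  offset <- attr(cond, "offset")
  d <- dim(session$F)
  nf <- d[2]; nt <- d[3]
  pre_open <- seq_len(session$epochs[["open"]] - 1L)

  dff_arr <- array(0, dim = d)
  ev_arr <- array(0, dim = d)
  f0 <- thr <- fp <- numeric(d[1])
  restored <- fb <- logical(d[1])
  excluded <- vector("list", d[1])
  for (i in seq_len(d[1])) {
    trace <- cond[i, ]
    b <- estimate_baseline(trace)
    if (b <= 0) {
      trace <- trace + offset[i]
      b <- estimate_baseline(trace)
      restored[i] <- TRUE
    }
    dff <- compute_dff(trace, b, neuron = i)
    det <- detect_events(matrix(dff, nrow = nf), pre_open,
                         mode = threshold_mode)
    f0[i] <- b
    thr[i] <- det$threshold
    fb[i] <- det$fallback
    excluded[[i]] <- det$excluded
    fp[i] <- false_positive_ratio(dff, det$threshold)
    dff_arr[i, , ] <- dff
    ev_arr[i, , ] <- det$events
  }
  structure(
    list(
      dff = dff_arr, events = ev_arr, f0 = f0, threshold = thr,
      fp_ratio = fp, baseline_restored = restored,
      threshold_fallback = fb, excluded_trials_pass1 = excluded,
      trials = session$trials, task = session$task,
      epochs = session$epochs
    ),
    class = "ca1_events"
  )
}

#' @export
print.ca1_events <- function(x, ...) {
  d <- dim(x$dff)
  cat("<ca1_events> ", d[1], " neurons x ", d[2], " frames x ", d[3],
      " trials\n  median threshold ", signif(median(x$threshold), 3),
      ", median false-positive ratio ",
      signif(median(x$fp_ratio, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}
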