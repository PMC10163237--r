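#' Write a session to disk as plain-text files
#'
#' Serializes a [ca1_session] into `dir/`: `trials.csv` (one row per trial;
#' lick times semicolon-joined, seconds from trial start), an optional
#' fluorescence matrix `fluorescence.csv` (frame-major rows: frame 1..F of
#' trial 1, then trial 2, ...; one column per neuron), `meta.json` (array
#' dims, frame rate, epoch frame indices -- 0-based in the file --,
#' category map, day) and, for synthetic sessions, `truth.csv`.
#'
#' @param session A [ca1_session].
#' @param dir Output directory (created if missing).
#' @param fluorescence Also write the (possibly large) fluorescence matrix
#'   (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, fluorescence = TRUE) {
  stopifnot(inherits(session, "ca1_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- session$trials
  tr$lick_times <- vapply(tr$lick_times, function(l) {
    paste(formatC(l, digits = 6, format = "g"), collapse = ";")
  }, character(1))
  readr::write_csv(tr, file.path(dir, "trials.csv"), progress = FALSE)
  d <- dim(session$F)
  meta <- list(
    n_neurons = d[1], n_frames = d[2], n_trials = d[3],
    frame_rate_hz = session$task$frame_rate_hz,
    day = session$day,
    stimuli = session$task$stimuli,
    category_map = as.list(session$task$category_map),
    grace_s = session$task$grace_s,
    window_open_s = session$task$window_open_s,
    opening_motion_s = session$task$opening_motion_s,
    iti_s = session$task$iti_s,
    pre_open_imaging_s = session$task$pre_open_imaging_s,
    post_close_imaging_s = session$task$post_close_imaging_s,
    epoch_frames_0based = as.list(session$epochs - 1L),
    time_convention = "seconds from trial start; frame indices 0-based"
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (fluorescence) {
    flat <- matrix(aperm(session$F, c(2, 3, 1)), nrow = d[2] * d[3])
    colnames(flat) <- paste0("n", seq_len(d[1]))
    readr::write_csv(tibble::as_tibble(flat),
                     file.path(dir, "fluorescence.csv"), progress = FALSE)
  }
  if (!is.null(session$truth)) {
    readr::write_csv(session$truth, file.path(dir, "truth.csv"),
                     progress = FALSE)
  }
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Session directory.
#' @param fluorescence Read the fluorescence matrix (default TRUE; FALSE
#'   loads behavior only, with a zero fluorescence array).
#' @return A [ca1_session].
#' @export
read_session <- function(dir, fluorescence = TRUE) {
  tpath <- file.path(dir, "trials.csv")
  mpath <- file.path(dir, "meta.json")
  for (p in c(tpath, mpath)) {
    if (!file.exists(p)) abort(paste0("missing session file: ", p))
  }
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  tr <- readr::read_csv(tpath, show_col_types = FALSE, progress = FALSE)
  need <- c("trial_idx", "day", "stimulus", "category", "t_open",
            "t_open_complete", "t_response", "t_close", "lick_times",
            "outcome", "rewarded")
  missing <- setdiff(need, names(tr))
  if (length(missing) > 0) {
    abort(paste0("trials.csv lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tr$lick_times <- lapply(tr$lick_times, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0) else
      as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  task <- task_spec(
    stimuli = meta$stimuli,
    category_map = unlist(meta$category_map),
    grace_s = meta$grace_s,
    window_open_s = meta$window_open_s,
    opening_motion_s = meta$opening_motion_s,
    iti_s = meta$iti_s,
    frame_rate_hz = meta$frame_rate_hz,
    pre_open_imaging_s = meta$pre_open_imaging_s,
    post_close_imaging_s = meta$post_close_imaging_s
  )
  d <- c(meta$n_neurons, meta$n_frames, meta$n_trials)
  if (task$n_frames != d[2]) {
    abort(sprintf("meta.json frame count %d does not match task timing (%d).",
                  d[2], task$n_frames))
  }
  ep <- unlist(meta$epoch_frames_0based) + 1L
  if (any(ep < 1) || any(ep > d[2]) || any(diff(ep) <= 0)) {
    abort("epoch frame indices out of range or not increasing.")
  }
  if (fluorescence) {
    fpath <- file.path(dir, "fluorescence.csv")
    if (!file.exists(fpath)) abort(paste0("missing session file: ", fpath))
    flat <- as.matrix(readr::read_csv(fpath, show_col_types = FALSE,
                                      progress = FALSE))
    if (nrow(flat) != d[2] * d[3] || ncol(flat) != d[1]) {
      abort(sprintf(
        "fluorescence.csv is %d x %d but meta.json implies %d rows (frames x trials, frame-major) x %d neuron columns.",
        nrow(flat), ncol(flat), d[2] * d[3], d[1]))
    }
    F <- aperm(array(flat, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  } else {
    F <- array(0, dim = d)
  }
  truth <- NULL
  tpath2 <- file.path(dir, "truth.csv")
  if (file.exists(tpath2)) {
    truth <- readr::read_csv(tpath2, show_col_types = FALSE,
                             progress = FALSE)
    class(truth) <- c("ca1_truth", class(truth))
  }
  ca1_session(trials = tr, F = F, task = task, truth = truth,
              day = meta$day)
}

#' Default pipeline configuration
#'
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @return Nested configuration list accepted by [run_pipeline()]; edit
#'   fields or serialize to YAML/JSON and back.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("ca1run")) {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = list(simulate = TRUE, behavior = TRUE, preprocess = TRUE,
                  selectivity = TRUE, reversal = TRUE, decoding = TRUE),
    simulate = list(
      n_days = 2, n_trials = 120, reversal = TRUE,
      n_reward = 6, n_noreward = 3, n_identity = 6, n_none = 25,
      amplitude = 1, event_rate = 2, stable = TRUE,
      write_fluorescence = FALSE
    ),
    preprocess = list(median_order = 3, drift_window = 900,
                      percentile = 0.05, threshold_mode = "median+3iqr"),
    selectivity = list(n_shuffles = 1000, restrict = "correct_high"),
    decoding = list(frame_stride = 6, n_perm = 200, cost = 1,
                    restrict = "all")
  )
}

read_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  allowed <- names(default_config())
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  utils::modifyList(default_config(), config)
}

#' Run the full synthetic-session analysis pipeline
#'
#' Orchestrates simulate -> behavior -> preprocess -> selectivity ->
#' reversal -> decoding on a generated multi-day data set, writing each
#' stage's tabular outputs under `out_dir` and a machine-readable run
#' report. The whole run is a pure function of (config, seed): identical
#' inputs give identical outputs.
#'
#' @param config A configuration list (see [default_config()]) or the path
#'   of a YAML/JSON file holding one. Unknown keys are rejected.
#' @return A `ca1_report` list (also written to `out_dir/report.json`):
#'   per-stage parameters, seeds, output files and wall-clock seconds.
#' @examples
#' \donttest{
#' cfg <- default_config(seed = 1)
#' cfg$simulate$n_trials <- 60
#' cfg$selectivity$n_shuffles <- 100
#' cfg$decoding$n_perm <- 0
#' rep <- run_pipeline(cfg)
#' names(rep$stages)
#' }
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- read_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("socialca1")),
                 seed = cfg$seed, out_dir = cfg$out_dir, stages = list())
  stage <- function(name, params, fun) {
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    report$stages[[name]] <<- list(
      params = params,
      seed = child_seed(cfg$seed, name),
      outputs = out$files,
      wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    out$value
  }

  task <- task_spec()
  sessions <- NULL; regmap <- NULL

  if (isTRUE(cfg$stages$simulate)) {
    sim <- cfg$simulate
    res <- stage("simulate", sim, function() {
      truth <- ground_truth(sim$n_reward, sim$n_noreward, sim$n_identity,
                            sim$n_none, stimuli = task$stimuli,
                            amplitude = sim$amplitude,
                            event_rate = sim$event_rate,
                            stable = sim$stable,
                            seed = child_seed(cfg$seed, "truth"))
      md <- generate_multiday(
        task, truth, n_days = sim$n_days,
        reversal_schedule = if (isTRUE(sim$reversal)) NULL else
          rep(list(task$category_map), sim$n_days),
        seed = child_seed(cfg$seed, "simulate"),
        n_trials = sim$n_trials
      )
      files <- character(0)
      for (d in seq_along(md$sessions)) {
        sd <- file.path(cfg$out_dir, sprintf("session_day%d", d))
        write_session(md$sessions[[d]], sd,
                      fluorescence = isTRUE(sim$write_fluorescence))
        files <- c(files, sd)
      }
      rp <- file.path(cfg$out_dir, "regmap.csv")
      readr::write_csv(md$regmap, rp, progress = FALSE)
      list(value = md, files = c(files, rp))
    })
    sessions <- res$sessions
    regmap <- res$regmap
  }
  if (is.null(sessions)) {
    abort("no input sessions: enable the simulate stage or load sessions.")
  }

  if (isTRUE(cfg$stages$behavior)) {
    stage("behavior", list(), function() {
      files <- character(0)
      for (d in seq_along(sessions)) {
        tr <- sessions[[d]]$trials
        hp <- find_high_performance(tr)
        out <- dplyr::mutate(compute_rates(tr, window = 50),
                             day = sessions[[d]]$day)
        f <- file.path(cfg$out_dir, sprintf("behavior_day%d.csv", d))
        readr::write_csv(out, f, progress = FALSE)
        files <- c(files, f)
      }
      list(value = NULL, files = files)
    })
  }

  events <- NULL
  if (isTRUE(cfg$stages$preprocess)) {
    pp <- cfg$preprocess
    events <- stage("preprocess", pp, function() {
      evs <- lapply(sessions, function(s) {
        preprocess_session(s, median_order = pp$median_order,
                           drift_window = pp$drift_window,
                           percentile = pp$percentile,
                           threshold_mode = pp$threshold_mode)
      })
      files <- character(0)
      for (d in seq_along(evs)) {
        e <- evs[[d]]
        f <- file.path(cfg$out_dir, sprintf("events_day%d.csv", d))
        readr::write_csv(tibble::tibble(
          neuron = seq_along(e$f0), f0 = e$f0, threshold = e$threshold,
          fp_ratio = e$fp_ratio, baseline_restored = e$baseline_restored,
          threshold_fallback = e$threshold_fallback
        ), f, progress = FALSE)
        files <- c(files, f)
      }
      list(value = evs, files = files)
    })
  }

  sel <- NULL
  if (isTRUE(cfg$stages$selectivity)) {
    if (is.null(events)) abort("selectivity stage requires preprocess.")
    sl <- cfg$selectivity
    sel <- stage("selectivity", sl, function() {
      res <- lapply(seq_along(events), function(d) {
        trial_type_selectivity(events[[d]], n_shuffles = sl$n_shuffles,
                               seed = child_seed(cfg$seed,
                                                 paste0("sel.", d)),
                               restrict = sl$restrict)
      })
      files <- character(0)
      for (d in seq_along(res)) {
        f <- file.path(cfg$out_dir, sprintf("selectivity_day%d.csv", d))
        readr::write_csv(res[[d]], f, progress = FALSE)
        files <- c(files, f)
      }
      js <- file.path(cfg$out_dir, "selectivity_summary.json")
      jsonlite::write_json(
        lapply(res, function(r) as.list(prop.table(table(r$label)))),
        js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      list(value = res, files = c(files, js))
    })
  }

  if (isTRUE(cfg$stages$reversal) && length(sessions) >= 2 &&
      !is.null(sel)) {
    stage("reversal", list(), function() {
      links <- regmap_links(regmap, 1, 2)
      rev_pair <- !identical(sessions[[1]]$category_map,
                             sessions[[2]]$category_map)
      cls <- classify_across_reversal(sel[[1]]$label, sel[[2]]$label,
                                      links = links, reversed = rev_pair)
      inf <- contingency_inference(cls)
      f1 <- file.path(cfg$out_dir, "reversal_classification.csv")
      readr::write_csv(cls$classification, f1, progress = FALSE)
      f2 <- file.path(cfg$out_dir, "reversal_inference.json")
      jsonlite::write_json(
        list(statistic = inf$statistic, df = inf$df, p_value = inf$p_value,
             planned = inf$planned),
        f2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      list(value = cls, files = c(f1, f2))
    })
  }

  if (isTRUE(cfg$stages$decoding)) {
    if (is.null(events)) abort("decoding stage requires preprocess.")
    dc <- cfg$decoding
    stage("decoding", dc, function() {
      e1 <- events[[1]]
      idx <- analysis_trials(e1$trials, dc$restrict)
      idx <- idx[balance_trials(e1$trials$category[idx],
                                seed = child_seed(cfg$seed, "balance"))]
      frames <- seq(1L, dim(e1$events)[2], by = dc$frame_stride)
      labels <- e1$trials$category[idx]
      spec <- decoder_spec(cost = dc$cost,
                           seed = child_seed(cfg$seed, "decode"))
      files <- character(0)
      if (dc$n_perm > 0) {
        ct <- cluster_permutation_test(e1, labels, frames = frames,
                                       n_perm = dc$n_perm, spec = spec,
                                       seed = child_seed(cfg$seed, "perm"),
                                       trial_idx = idx)
        dec <- ct$accuracy
        f2 <- file.path(cfg$out_dir, "decoding_clusters.json")
        jsonlite::write_json(ct$clusters, f2, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
        files <- c(files, f2)
      } else {
        dec <- decode_timecourse(e1, labels, frames = frames, spec = spec,
                                 trial_idx = idx)
      }
      f1 <- file.path(cfg$out_dir, "decoding_day1.csv")
      readr::write_csv(tidy(dec), f1, progress = FALSE)
      files <- c(f1, files)
      if (length(events) >= 2) {
        links <- regmap_links(regmap, 1, 2)
        e2 <- events[[2]]
        cd <- crossday_decode(e1, e2, e1$trials$category,
                              e2$trials$category, links = links,
                              frames = frames, spec = spec)
        f3 <- file.path(cfg$out_dir, "decoding_crossday.csv")
        readr::write_csv(tidy(cd), f3, progress = FALSE)
        files <- c(files, f3)
      }
      list(value = dec, files = files)
    })
  }

  class(report) <- "ca1_report"
  jsonlite::write_json(unclass(report),
                       file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  report
}

#' @export
print.ca1_report <- function(x, ...) {
  cat("<ca1_report> seed ", x$seed, ", ", length(x$stages), " stage(s): ",
      paste(names(x$stages), collapse = ", "), "\n", sep = "")
  invisible(x)
}
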