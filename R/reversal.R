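#' Classify registered neurons across a contingency-reversed session pair
#'
#' Over a reversed pair, neurons keeping their Go (or NoGo) preference track
#' the expected outcome and are reward-selective (or no-reward-selective);
#' neurons whose Go/NoGo preference flips have kept their *stimulus* tuning
#' through the reversal and are mouse-selective. Neurons non-selective on
#' either day are unclassified.
#'
#' @param labels_day1,labels_day2 Per-neuron selectivity labels (`"go"`,
#'   `"nogo"`, `"none"`), in each day's local neuron order (e.g. the `label`
#'   column of [trial_type_selectivity()]).
#' @param links Registration links for the pair (tibble with `index_i`,
#'   `index_j`, e.g. from [regmap_links()]). Default: identity mapping
#'   (requires equal lengths).
#' @param reversed The pair is contingency-reversed (default TRUE; with
#'   FALSE, preserved preference means stimulus tuning instead, and class
#'   names follow the non-reversed reading).
#' @return A `ca1_reversal` list: `classification` tibble (one row per
#'   linked neuron: `index_i`, `index_j`, `label_day1`, `label_day2`,
#'   `class`), `n_unlinked` neurons of day 1 without a link, and the 3x3
#'   `table` of day-1 by day-2 labels.
#' @export
classify_across_reversal <- function(labels_day1, labels_day2, links = NULL,
                                     reversed = TRUE) {
  lv <- c("go", "nogo", "none")
  if (!all(labels_day1 %in% lv) || !all(labels_day2 %in% lv)) {
    abort("labels must be 'go', 'nogo' or 'none'.")
  }
  if (is.null(links)) {
    if (length(labels_day1) != length(labels_day2)) {
      abort("label vectors differ in length; supply `links`.")
    }
    links <- tibble::tibble(index_i = seq_along(labels_day1),
                            index_j = seq_along(labels_day2))
  }
  l1 <- labels_day1[links$index_i]
  l2 <- labels_day2[links$index_j]
  cls <- dplyr::case_when(
    l1 == "none" | l2 == "none" ~ "none",
    reversed & l1 == "go" & l2 == "go" ~ "reward-selective",
    reversed & l1 == "nogo" & l2 == "nogo" ~ "no-reward-selective",
    reversed & l1 != l2 ~ "mouse-selective",
    !reversed & l1 == l2 ~ "stimulus-stable",
    TRUE ~ "stimulus-reversed"
  )
  tab <- table(factor(l1, levels = lv), factor(l2, levels = lv),
               dnn = c("day1", "day2"))
  structure(
    list(
      classification = tibble::tibble(
        index_i = links$index_i, index_j = links$index_j,
        label_day1 = l1, label_day2 = l2, class = cls
      ),
      n_unlinked = length(labels_day1) - nrow(links),
      table = tab,
      reversed = reversed
    ),
    class = "ca1_reversal"
  )
}

#' @export
print.ca1_reversal <- function(x, ...) {
  cat("<ca1_reversal> ", nrow(x$classification), " linked neurons (",
      x$n_unlinked, " unlinked)\n", sep = "")
  print(table(x$classification$class))
  invisible(x)
}

#' Chi-square independence test of the 3x3 day-1 by day-2 label table
#'
#' Tests whether Go-preferring, NoGo-preferring and non-selective neurons on
#' day 1 are randomly reassorted to the three categories on day 2 (no
#' continuity correction; expected counts from the margins). Post-hoc cell
#' tests use adjusted (Haberman) residuals
#' `(O - E) / sqrt(E (1 - row fraction) (1 - column fraction))`; the four
#' planned cells -- preference maintained (go->go, nogo->nogo) and reversed
#' (go->nogo, nogo->go) -- are tested two-sided against the normal at the
#' Bonferroni-corrected criterion p < 0.0125.
#'
#' @param x A `ca1_reversal`, a 3x3 count table/matrix, or a day-1 label
#'   vector (then `labels_day2` is required).
#' @param labels_day2 Day-2 labels when `x` is a label vector.
#' @param alpha Planned-comparison criterion (0.0125).
#' @return A `ca1_contingency` list: `table`, `statistic`, `df`, `p_value`,
#'   `expected`, `adjusted_residuals`, and `planned` (tibble of the four
#'   planned cells with residual, p and verdict). Cells whose row *and*
#'   column margins are zero are dropped from `planned`.
#' @export
contingency_inference <- function(x, labels_day2 = NULL, alpha = 0.0125) {
  lv <- c("go", "nogo", "none")
  tab <- if (inherits(x, "ca1_reversal")) {
    x$table
  } else if (is.table(x) || is.matrix(x)) {
    stopifnot(all(dim(x) == c(3, 3)))
    x
  } else {
    stopifnot(!is.null(labels_day2))
    table(factor(x, levels = lv), factor(labels_day2, levels = lv),
          dnn = c("day1", "day2"))
  }
  tab <- as.table(tab)
  n <- sum(tab)
  rm_ <- rowSums(tab); cm <- colSums(tab)
  expected <- outer(rm_, cm) / n
  keep_r <- rm_ > 0; keep_c <- cm > 0
  suppressWarnings(
    chi <- chisq.test(tab[keep_r, keep_c, drop = FALSE], correct = FALSE)
  )
  if (any(expected[keep_r, keep_c] < 5)) {
    warn("some expected counts are below 5; chi-square may be unreliable.")
  }
  # adjusted residuals on the full table (NA where a margin is empty)
  adj <- matrix(NA_real_, 3, 3, dimnames = dimnames(tab))
  for (i in 1:3) {
    for (j in 1:3) {
      denom <- sqrt(expected[i, j] * (1 - rm_[i] / n) * (1 - cm[j] / n))
      if (is.finite(denom) && denom > 0) {
        adj[i, j] <- (tab[i, j] - expected[i, j]) / denom
      }
    }
  }
  planned_cells <- list(c("go", "go"), c("nogo", "nogo"),
                        c("go", "nogo"), c("nogo", "go"))
  planned <- purrr::map_dfr(planned_cells, function(cell) {
    i <- cell[1]; j <- cell[2]
    if (rm_[i] == 0 && cm[j] == 0) return(NULL)
    r <- adj[i, j]
    p <- if (is.na(r)) NA_real_ else 2 * pnorm(-abs(r))
    tibble::tibble(day1 = i, day2 = j, observed = as.numeric(tab[i, j]),
                   expected = expected[i, j], adj_residual = r, p_value = p,
                   significant = !is.na(p) & p < alpha)
  })
  structure(
    list(table = tab, statistic = unname(chi$statistic),
         df = unname(chi$parameter), p_value = chi$p.value,
         expected = expected, adjusted_residuals = adj, planned = planned,
         alpha = alpha),
    class = "ca1_contingency"
  )
}

#' @export
print.ca1_contingency <- function(x, ...) {
  cat("<ca1_contingency> X-squared = ", signif(x$statistic, 4), ", df = ",
      x$df, ", p = ", signif(x$p_value, 3), "\n", sep = "")
  print(x$planned)
  invisible(x)
}

#' Cross-day stability of selective neurons against chance
#'
#' Follows day-1 selective neurons of a given preference forward: the stable
#' fraction is the proportion with the same significant preference on day 2,
#' the reversed fraction the proportion with the opposite significant
#' preference. The chance level for the stable fraction is the overall
#' proportion of day-2 neurons carrying that preference (and likewise for
#' the reversed fraction).
#'
#' @param labels_day1,labels_day2 Per-neuron labels in local order.
#' @param links Registration links (as in [classify_across_reversal()]).
#' @param preference `"go"` or `"nogo"`: the day-1 preference to follow.
#' @return Tibble with `preference`, `n_day1` (selective day-1 neurons),
#'   `stable_fraction`, `reversed_fraction`, `chance_stable`,
#'   `chance_reversed`. Fractions are `NA` when no day-1 neuron is
#'   selective.
#' @export
stability_analysis <- function(labels_day1, labels_day2, links = NULL,
                               preference = c("go", "nogo")) {
  preference <- match.arg(preference)
  other <- setdiff(c("go", "nogo"), preference)
  if (is.null(links)) {
    links <- tibble::tibble(index_i = seq_along(labels_day1),
                            index_j = seq_along(labels_day2))
  }
  l1 <- labels_day1[links$index_i]
  l2 <- labels_day2[links$index_j]
  sel <- which(l1 == preference)
  n2 <- length(l2)
  tibble::tibble(
    preference = preference,
    n_day1 = length(sel),
    stable_fraction = if (length(sel)) mean(l2[sel] == preference) else NA_real_,
    reversed_fraction = if (length(sel)) mean(l2[sel] == other) else NA_real_,
    chance_stable = mean(l2 == preference),
    chance_reversed = mean(l2 == other)
  )
}
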