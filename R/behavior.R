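# Behavioural scoring: perception rate, orientation accuracy, false
# positives, binomial test, reaction-time comparison.

#' Score target perception from events and keypresses
#'
#' A target counts as perceived when at least one keypress lands in
#' `(onset, onset + window_ms]`. Presses are credited greedily: walking
#' through targets in onset order, each target takes the earliest
#' still-unmatched press inside its window, so no press answers two
#' targets. Perception rate is perceived / presented per field; the false
#' positive rate is unmatched presses over total presses (a whole-session
#' quantity, repeated on every row; `NA` when there are no presses);
#' reaction time is the matched press minus onset.
#'
#' @param events Event tibble (`onset_ms`, `event_class`, `field`);
#'   targets are the classes starting with `"target"`.
#' @param responses Response tibble (`press_ms`, `key`), same clock.
#' @param window_ms Response window after onset, ms.
#' @return Tibble with one row per field: `field`, `n_targets`,
#'   `n_perceived`, `perception_rate`, `false_positive_rate`, `rts`
#'   (list-column of reaction times in s). The press-to-target match table
#'   is attached as attribute `"matches"`.
#' @export
score_perception <- function(events, responses, window_ms = 5000) {
  targets <- dplyr::arrange(
    dplyr::filter(events, startsWith(.data$event_class, "target")),
    .data$onset_ms
  )
  if (nrow(targets) == 0) {
    rlang::abort("no presented targets", class = "oculaware_data_error")
  }
  presses <- sort(responses$press_ms)
  keys <- responses$key[order(responses$press_ms)]
  used <- rep(FALSE, length(presses))
  match_press <- rep(NA_real_, nrow(targets))
  match_key <- rep(NA_character_, nrow(targets))
  for (i in seq_len(nrow(targets))) {
    on <- targets$onset_ms[i]
    j <- which(!used & presses > on & presses <= on + window_ms)
    if (length(j) > 0) {
      j <- j[1]
      used[j] <- TRUE
      match_press[i] <- presses[j]
      match_key[i] <- keys[j]
    }
  }
  matches <- dplyr::mutate(
    targets,
    press_ms = match_press, key = match_key,
    rt_s = (match_press - .data$onset_ms) / 1000,
    perceived = !is.na(match_press)
  )
  fpr <- if (length(presses) == 0) NA_real_ else mean(!used)
  out <- dplyr::summarise(
    dplyr::group_by(matches, .data$field),
    n_targets = dplyr::n(),
    n_perceived = sum(.data$perceived),
    perception_rate = mean(.data$perceived),
    rts = list(.data$rt_s[.data$perceived]),
    .groups = "drop"
  )
  out$false_positive_rate <- fpr
  out <- dplyr::relocate(out, "false_positive_rate", .after = "perception_rate")
  attr(out, "matches") <- matches
  out
}

#' Orientation discrimination accuracy of perceived targets
#'
#' Accuracy is correct-orientation presses over perceived targets, per
#' field, where the correct key follows the target class
#' (`target-plus` -> `plus`, `target-x` -> `x`). Undefined (`NA`) for the
#' one-target task version, when fewer than `min_perceived` targets were
#' perceived in a field, or when the summary has no match table.
#'
#' @param perception Result of [score_perception()] (its `"matches"`
#'   attribute is used), or a matches tibble.
#' @param min_perceived Minimum perceived-target count to report accuracy.
#' @return Tibble per field: `n_perceived`, `n_correct`, `accuracy`.
#' @export
score_orientation <- function(perception, min_perceived = 1) {
  matches <- if (is.data.frame(perception) &&
                 !is.null(attr(perception, "matches"))) {
    attr(perception, "matches")
  } else {
    perception
  }
  stopifnot(is.data.frame(matches), "perceived" %in% names(matches))
  one_target <- length(unique(matches$event_class)) < 2
  correct_key <- ifelse(matches$event_class == "target-plus", "plus", "x")
  matches$correct <- matches$perceived & matches$key == correct_key
  out <- dplyr::summarise(
    dplyr::group_by(matches, .data$field),
    n_perceived = sum(.data$perceived),
    n_correct = sum(.data$correct, na.rm = TRUE),
    .groups = "drop"
  )
  out$accuracy <- ifelse(
    !one_target & out$n_perceived >= min_perceived,
    out$n_correct / out$n_perceived, NA_real_
  )
  if (one_target) {
    attr(out, "undefined_reason") <- "one-target task version"
  }
  out
}

#' Exact one-sided binomial test of above-chance performance
#'
#' Upper-tail probability \eqn{P(X \ge k)} for \eqn{X \sim Binomial(n, p0)}.
#'
#' @param k Successes observed.
#' @param n Trials.
#' @param p0 Chance probability.
#' @return The exact one-sided p-value.
#' @export
binomial_above_chance <- function(k, n, p0 = 0.5) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k < 0 || n < 1 || k > n || k != round(k) || n != round(n)) {
    rlang::abort("`k` and `n` must be integer counts with 0 <= k <= n")
  }
  stopifnot(p0 >= 0, p0 <= 1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Compare two reaction-time samples
#'
#' Paired: Wilcoxon signed-rank on the per-trial differences, trimming both
#' samples to the common length in trial order when they differ (flagged in
#' the output). Unpaired: Wilcoxon rank-sum. Two-sided.
#'
#' @param rts_a,rts_b Numeric reaction times in s.
#' @param paired Use the matched-pairs signed-rank test?
#' @return One-row tibble: `method`, `n_a`, `n_b`, `statistic`, `p_value`,
#'   `note`.
#' @export
compare_rt <- function(rts_a, rts_b, paired = TRUE) {
  rts_a <- rts_a[!is.na(rts_a)]
  rts_b <- rts_b[!is.na(rts_b)]
  if (length(rts_a) < 2 || length(rts_b) < 2) {
    return(tibble::tibble(method = NA_character_, n_a = length(rts_a),
                          n_b = length(rts_b), statistic = NA_real_,
                          p_value = NA_real_,
                          note = "skipped: fewer than 2 observations per side"))
  }
  note <- NA_character_
  if (paired) {
    m <- min(length(rts_a), length(rts_b))
    if (length(rts_a) != length(rts_b)) {
      note <- sprintf("unequal lengths trimmed to %d by trial order", m)
    }
    sr <- signed_rank_test(rts_a[seq_len(m)] - rts_b[seq_len(m)],
                           alternative = "two.sided")
    tibble::tibble(method = "signed-rank (paired)", n_a = m, n_b = m,
                   statistic = sr$statistic, p_value = sr$p_value, note = note)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(rts_a, rts_b))
    tibble::tibble(method = "rank-sum (unpaired)",
                   n_a = length(rts_a), n_b = length(rts_b),
                   statistic = unname(wt$statistic), p_value = wt$p.value,
                   note = note)
  }
}
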