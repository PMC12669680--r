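# Group-level statistics on per-participant classification accuracies.

#' Group statistics on classification accuracy
#'
#' Runs the accuracy test battery over a per-participant table: one-sided
#' Wilcoxon signed-rank tests of accuracy against each participant's own
#' chance level (one per condition), two-sided paired signed-rank tests
#' for within-group condition contrasts (e.g. left vs right, sighted vs
#' blind), and one-sided Mann-Whitney tests for between-group contrasts
#' within a condition (e.g. blind-field accuracy, aware vs unaware).
#' Holm-Bonferroni correction is applied separately within the
#' against-chance family and the cross-condition family. Tests with fewer
#' than two observations per side are reported as skipped.
#'
#' @param data Tibble with columns `participant`, `condition`, `accuracy`,
#'   `chance`, and optionally `group`.
#' @param paired_contrasts List of length-2 character vectors of condition
#'   names compared within participant.
#' @param group_contrasts List of lists `list(condition =, groups = c(a, b))`;
#'   tested one-sided, first group greater.
#' @return Tibble with `family`, `test`, `n`, `statistic`, `p_value`,
#'   `p_adj`, `skipped`.
#' @export
group_accuracy_stats <- function(data, paired_contrasts = list(),
                                 group_contrasts = list()) {
  stopifnot(all(c("participant", "condition", "accuracy", "chance") %in%
                  names(data)))
  rows <- list()
  skip_row <- function(family, test, n, reason) {
    tibble::tibble(family = family, test = test, n = n,
                   statistic = NA_real_, p_value = NA_real_,
                   skipped = reason)
  }
  for (cond in unique(data$condition)) {
    d <- dplyr::filter(data, .data$condition == cond)
    test_name <- paste0(cond, " vs chance")
    if (nrow(d) < 2) {
      rows[[length(rows) + 1]] <- skip_row("vs-chance", test_name, nrow(d),
                                           "fewer than 2 participants")
      next
    }
    sr <- signed_rank_test(d$accuracy - d$chance, alternative = "greater")
    rows[[length(rows) + 1]] <- tibble::tibble(
      family = "vs-chance", test = test_name, n = nrow(d),
      statistic = sr$statistic, p_value = sr$p_value, skipped = NA_character_
    )
  }
  for (ct in paired_contrasts) {
    test_name <- paste(ct[1], "vs", ct[2])
    wide <- dplyr::inner_join(
      dplyr::filter(data, .data$condition == ct[1]),
      dplyr::filter(data, .data$condition == ct[2]),
      by = "participant", suffix = c("_a", "_b")
    )
    if (nrow(wide) < 2) {
      rows[[length(rows) + 1]] <- skip_row("cross-condition", test_name,
                                           nrow(wide), "fewer than 2 pairs")
      next
    }
    sr <- signed_rank_test(wide$accuracy_a - wide$accuracy_b,
                           alternative = "two.sided")
    rows[[length(rows) + 1]] <- tibble::tibble(
      family = "cross-condition", test = test_name, n = nrow(wide),
      statistic = sr$statistic, p_value = sr$p_value, skipped = NA_character_
    )
  }
  for (gc in group_contrasts) {
    test_name <- sprintf("%s: %s vs %s", gc$condition, gc$groups[1], gc$groups[2])
    stopifnot("group" %in% names(data))
    a <- dplyr::filter(data, .data$condition == gc$condition,
                       .data$group == gc$groups[1])$accuracy
    b <- dplyr::filter(data, .data$condition == gc$condition,
                       .data$group == gc$groups[2])$accuracy
    if (length(a) < 2 || length(b) < 2) {
      rows[[length(rows) + 1]] <- skip_row("cross-condition", test_name,
                                           length(a) + length(b),
                                           "fewer than 2 observations per group")
      next
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "greater"))
    rows[[length(rows) + 1]] <- tibble::tibble(
      family = "cross-condition", test = test_name, n = length(a) + length(b),
      statistic = unname(wt$statistic), p_value = wt$p.value,
      skipped = NA_character_
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::group_by(out, .data$family)
  out <- dplyr::mutate(out, p_adj = holm_adjust(.data$p_value))
  dplyr::ungroup(out)
}

#' Holm-Bonferroni adjustment that tolerates missing entries
#'
#' @param p Vector of raw p-values (`NA` for skipped tests).
#' @return Adjusted p-values, `NA` preserved.
#' @export
holm_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "holm")
  out
}
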