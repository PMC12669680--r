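# Brightness-comparison scoring and group tests.

#' Score brightness-comparison choice records
#'
#' Applies the pairwise point rule per trial: the stimulus reported
#' brighter gets 1 point, both get 0.5 when reported equally bright, the
#' dimmer gets 0. With 10 trials per pairing each stimulus appears in 20
#' comparisons, so totals range from 0 (always dimmer) to 20 (always
#' brighter). With a `participant` column present, per-participant totals
#' feed a Friedman test over the three stimuli followed by post-hoc paired
#' signed-rank tests (glare vs nonglare, nonglare vs isoluminant) with
#' Holm-Bonferroni correction; tests are skipped with a reason when fewer
#' than two participants (or an empty pairing) are available.
#'
#' @param choices Choice tibble from [generate_brightness_responses()]
#'   (columns `stim_first`, `stim_second`, `choice`), optionally with a
#'   `participant` column.
#' @return A `brightness_scores` list: `scores` (participant, stimulus,
#'   points, n_comparisons) and `tests` (Friedman and post-hoc rows).
#' @export
score_brightness <- function(choices) {
  stopifnot(all(c("stim_first", "stim_second", "choice") %in% names(choices)))
  bad <- setdiff(unique(c(choices$stim_first, choices$stim_second)),
                 brightness_stimuli)
  if (length(bad) > 0) {
    rlang::abort(paste("unknown stimulus identity:", paste(bad, collapse = ", ")),
                 class = "oculaware_config_error")
  }
  if (!"participant" %in% names(choices)) choices$participant <- "p1"
  pts <- dplyr::bind_rows(
    dplyr::transmute(
      choices, .data$participant, stimulus = .data$stim_first,
      points = dplyr::case_when(
        choice == "first-brighter" ~ 1,
        choice == "equal" ~ 0.5,
        TRUE ~ 0
      )
    ),
    dplyr::transmute(
      choices, .data$participant, stimulus = .data$stim_second,
      points = dplyr::case_when(
        choice == "second-brighter" ~ 1,
        choice == "equal" ~ 0.5,
        TRUE ~ 0
      )
    )
  )
  scores <- dplyr::summarise(
    dplyr::group_by(pts, .data$participant, .data$stimulus),
    points = sum(.data$points), n_comparisons = dplyr::n(), .groups = "drop"
  )
  # ensure all three stimuli appear even at zero trials
  scores <- tidyr::complete(scores, .data$participant,
                            stimulus = brightness_stimuli,
                            fill = list(points = 0, n_comparisons = 0))
  tests <- brightness_tests(scores)
  structure(list(scores = scores, tests = tests), class = "brightness_scores")
}

brightness_tests <- function(scores) {
  wide <- tidyr::pivot_wider(scores[, c("participant", "stimulus", "points")],
                             names_from = "stimulus", values_from = "points")
  n_p <- nrow(wide)
  if (n_p < 2) {
    return(tibble::tibble(
      test = c("friedman", "glare vs nonglare", "nonglare vs isoluminant"),
      statistic = NA_real_, df = NA_real_, p_value = NA_real_,
      p_adj = NA_real_, skipped = "fewer than 2 participants"
    ))
  }
  m <- as.matrix(wide[, brightness_stimuli])
  fr <- stats::friedman.test(m)
  posthoc <- list(c("glare", "nonglare"), c("nonglare", "isoluminant"))
  ph <- purrr::map_dfr(posthoc, function(p) {
    sr <- signed_rank_test(wide[[p[1]]] - wide[[p[2]]],
                           alternative = "two.sided")
    tibble::tibble(test = paste(p[1], "vs", p[2]),
                   statistic = sr$statistic, df = NA_real_,
                   p_value = sr$p_value)
  })
  ph$p_adj <- holm_adjust(ph$p_value)
  dplyr::bind_rows(
    tibble::tibble(test = "friedman", statistic = unname(fr$statistic),
                   df = unname(fr$parameter), p_value = fr$p.value,
                   p_adj = NA_real_),
    ph
  ) |>
    dplyr::mutate(skipped = NA_character_)
}

#' @export
print.brightness_scores <- function(x, ...) {
  cat("<brightness_scores>\n")
  print(x$scores, n = 6)
  invisible(x)
}

#' @export
tidy.brightness_scores <- function(x, ...) x$scores

#' @export
glance.brightness_scores <- function(x, ...) x$tests
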