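# Stimulus- and blank-locked epoch extraction, baselining, exclusion rules
# and fraction timecourses.

#' Epoch window definition
#'
#' The eye-metric analysis uses epochs centered at the event with a
#' symmetric inclusive grid of `2 * half_ms + 1` samples (18,001 samples at
#' 1000 Hz for the default 9000-ms half-width), an analysis interval of
#' -1000 to +6000 ms, and a 1000-ms pre-event baseline.
#'
#' @param half_ms Half-width of the epoch in ms.
#' @param analysis_start_ms,analysis_end_ms Analysis interval bounds in ms.
#' @param baseline_ms Pre-event baseline length in ms.
#' @return List of class `epoch_window`.
#' @export
epoch_window <- function(half_ms = 9000, analysis_start_ms = NULL,
                         analysis_end_ms = NULL, baseline_ms = NULL) {
  analysis_start_ms <- analysis_start_ms %||% max(-1000, -half_ms)
  analysis_end_ms <- analysis_end_ms %||% min(6000, half_ms)
  baseline_ms <- baseline_ms %||% min(1000, half_ms)
  stopifnot(half_ms >= 1, baseline_ms >= 1,
            analysis_start_ms >= -half_ms, analysis_end_ms <= half_ms,
            analysis_start_ms < analysis_end_ms, baseline_ms <= half_ms)
  structure(list(half_ms = half_ms, analysis_start_ms = analysis_start_ms,
                 analysis_end_ms = analysis_end_ms, baseline_ms = baseline_ms),
            class = "epoch_window")
}

#' Sample one blank event per stimulus
#'
#' Draws, for every stimulus, a stimulus-free control time uniformly from
#' the interstimulus interval: between 4000 and 7000 ms after the stimulus
#' onset (i.e. at least 1000 ms after stimulus offset), no later than
#' 1000 ms before the next stimulus onset, and before the end of the task
#' block. The blank inherits the stimulus's class and field labels so that
#' every stimulus epoch has a paired blank epoch. Stimuli whose admissible
#' interval is empty get no blank; they are listed in the `omitted`
#' attribute.
#'
#' @param events Stimulus event tibble (`onset_ms`, `event_class`, `field`,
#'   `block`, `event_id`), sorted by onset within block.
#' @param block_end_ms Numeric vector of block end times, one per block.
#' @param seed Seed for the blank-time substream.
#' @param lead_ms,max_lag_ms Admissible window relative to stimulus onset.
#' @param guard_ms Minimum gap before the next stimulus onset.
#' @return Tibble of blank events with `is_blank = TRUE` and `pair_id`
#'   pointing at the paired stimulus `event_id`.
#' @export
sample_blank_events <- function(events, block_end_ms, seed = 1,
                                lead_ms = 4000, max_lag_ms = 7000,
                                guard_ms = 1000) {
  stopifnot(nrow(events) >= 1)
  set.seed(as.integer(seed))
  events <- dplyr::arrange(events, .data$block, .data$onset_ms)
  n <- nrow(events)
  lower <- events$onset_ms + lead_ms
  upper <- events$onset_ms + max_lag_ms
  next_onset <- c(events$onset_ms[-1], NA)
  same_block <- c(events$block[-1] == events$block[-n], FALSE)
  upper <- ifelse(same_block & !is.na(next_onset),
                  pmin(upper, next_onset - guard_ms), upper)
  upper <- pmin(upper, block_end_ms[events$block])
  ok <- upper >= lower
  t_blank <- rep(NA_real_, n)
  t_blank[ok] <- round(stats::runif(sum(ok), lower[ok], upper[ok]))
  blanks <- tibble::tibble(
    onset_ms = t_blank[ok],
    event_class = events$event_class[ok],
    field = events$field[ok],
    block = events$block[ok],
    event_id = max(events$event_id) + seq_len(sum(ok)),
    is_blank = TRUE,
    pair_id = events$event_id[ok]
  )
  attr(blanks, "omitted") <- events$event_id[!ok]
  blanks
}

new_epoch_set <- function(data, offsets_ms, meta, window, kind, baselined) {
  structure(
    list(data = data, offsets_ms = offsets_ms, meta = meta,
         included = rep(TRUE, nrow(meta)),
         exclusion_reason = rep(NA_character_, nrow(meta)),
         window = window, kind = kind, baselined = baselined),
    class = "epoch_set"
  )
}

#' Extract event-locked epochs from a timecourse
#'
#' Segments a sample-aligned timecourse into epochs centered at each event
#' onset on the window's inclusive symmetric grid. Samples outside the
#' recording are padded as missing. With `baseline = TRUE` the mean of the
#' `baseline_ms` samples immediately preceding the event is subtracted per
#' epoch; binary timecourses are never baselined.
#'
#' @param x Either a tibble with `t_ms` and the `signal` column on a 1-ms
#'   grid, or an `event_timecourse`.
#' @param events Event tibble (stimuli, blanks, or both) with `onset_ms`;
#'   `event_id`, `pair_id`, `event_class`, `field`, `block`, `is_blank` are
#'   carried into the epoch metadata when present.
#' @param window An [epoch_window()].
#' @param signal Column of `x` to epoch when `x` is a tibble.
#' @param baseline Subtract the pre-event baseline mean?
#' @return An `epoch_set`: epochs x samples matrix, per-sample offsets,
#'   per-epoch metadata and an all-`TRUE` inclusion mask.
#' @export
extract_epochs <- function(x, events, window = epoch_window(),
                           signal = "pupil", baseline = FALSE) {
  stopifnot(inherits(window, "epoch_window"))
  if (inherits(x, "event_timecourse")) {
    v <- as.numeric(x$values)
    t0 <- x$t0
    kind <- x$kind
    if (baseline) {
      rlang::abort("binary timecourses are never baselined")
    }
  } else {
    stopifnot("t_ms" %in% names(x), signal %in% names(x))
    v <- x[[signal]]
    t0 <- x$t_ms[1]
    kind <- signal
  }
  offsets_ms <- seq(-window$half_ms, window$half_ms)
  col_or <- function(nm, default) {
    if (nm %in% names(events)) events[[nm]] else default
  }
  ids <- col_or("event_id", seq_len(nrow(events)))
  meta <- tibble::tibble(
    event_id = ids,
    pair_id = col_or("pair_id", ids),
    onset_ms = events$onset_ms,
    event_class = col_or("event_class", NA_character_),
    field = col_or("field", NA_character_),
    block = col_or("block", NA_integer_),
    is_blank = col_or("is_blank", FALSE)
  )
  n_e <- nrow(meta)
  n_s <- length(offsets_ms)
  if (n_e == 0) {
    return(new_epoch_set(matrix(numeric(0), 0, n_s), offsets_ms, meta,
                         window, kind, baseline))
  }
  centre_idx <- meta$onset_ms - t0 + 1
  idx <- outer(centre_idx, offsets_ms, "+")
  bad <- idx < 1 | idx > length(v)
  idx[bad] <- 1L
  data <- matrix(v[idx], nrow = n_e, ncol = n_s)
  data[bad] <- NA_real_
  if (baseline) {
    bl_cols <- which(offsets_ms >= -window$baseline_ms & offsets_ms <= -1)
    bl <- rowMeans(data[, bl_cols, drop = FALSE], na.rm = TRUE)
    bl[is.nan(bl)] <- 0
    data <- data - bl
  }
  new_epoch_set(data, offsets_ms, meta, window, kind, baseline)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set: %s%s> %d epochs x %d samples, %d included\n",
              x$kind, if (x$baselined) ", baselined" else "",
              nrow(x$data), ncol(x$data), sum(x$included)))
  invisible(x)
}

#' @export
tidy.epoch_set <- function(x, ...) {
  dplyr::mutate(x$meta, included = x$included,
                exclusion_reason = x$exclusion_reason)
}

#' @export
glance.epoch_set <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, n_epochs = nrow(x$data), n_included = sum(x$included),
    n_samples = ncol(x$data), baselined = x$baselined,
    exclusion_fraction = 1 - sum(x$included) / max(1, nrow(x$data))
  )
}

analysis_cols <- function(x) {
  which(x$offsets_ms >= x$window$analysis_start_ms &
          x$offsets_ms <= x$window$analysis_end_ms)
}

#' Exclude pupil epochs with extreme values or excessive missingness
#'
#' An epoch is excluded when, within the analysis interval (-1000 to
#' +6000 ms by default), any pupil value exceeds `extreme_threshold`
#' (recorder units; 1750 by default, on the raw un-baselined scale) or the
#' fraction of missing samples is strictly greater than `missing_frac`.
#'
#' @param epochs Pupil `epoch_set` (typically baselined).
#' @param raw Optional un-baselined pupil `epoch_set` on the raw recorder
#'   scale for the extreme-value check; defaults to `epochs`.
#' @param missing Optional `epoch_set` of the pre-interpolation missingness
#'   mask (1 = missing) for the missing-fraction check; defaults to `NA`s
#'   in the value matrix used.
#' @param extreme_threshold Extreme pupil value, recorder units.
#' @param missing_frac Exclusion threshold on the missing fraction.
#' @return The `epoch_set` with its inclusion mask and reasons updated.
#' @export
apply_pupil_exclusion <- function(epochs, raw = NULL, missing = NULL,
                                  extreme_threshold = 1750,
                                  missing_frac = 0.5) {
  stopifnot(inherits(epochs, "epoch_set"))
  vals <- if (!is.null(raw)) raw$data else epochs$data
  cols <- analysis_cols(epochs)
  extreme <- apply(vals[, cols, drop = FALSE], 1,
                   function(r) any(r > extreme_threshold, na.rm = TRUE))
  miss_mat <- if (!is.null(missing)) missing$data[, cols, drop = FALSE] > 0
              else is.na(vals[, cols, drop = FALSE])
  frac <- rowMeans(miss_mat)
  excl_missing <- frac > missing_frac
  reason <- ifelse(extreme, "extreme",
                   ifelse(excl_missing, "missing", NA_character_))
  epochs$included <- epochs$included & is.na(reason)
  epochs$exclusion_reason <- ifelse(is.na(epochs$exclusion_reason),
                                    reason, epochs$exclusion_reason)
  epochs
}

#' Exclude binary epochs with lost tracking
#'
#' An epoch is excluded when tracking is absent for strictly more than
#' `zero_frac` of the analysis-interval samples. Tracking validity is
#' supplied as a parallel `epoch_set` extracted from the recording's
#' validity flag (1 = tracked). The `literal` variant instead counts
#' zeros of the binary event timecourse itself, which additionally
#' penalises epochs that merely contain few events.
#'
#' @param epochs Binary `epoch_set` (blink or microsaccade).
#' @param validity `epoch_set` of the tracking-validity flag; required
#'   unless `literal = TRUE`.
#' @param zero_frac Exclusion threshold.
#' @param literal Count zeros of the event timecourse itself.
#' @return The `epoch_set` with its inclusion mask updated.
#' @export
apply_binary_exclusion <- function(epochs, validity = NULL, zero_frac = 0.5,
                                   literal = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  cols <- analysis_cols(epochs)
  if (literal) {
    mat <- epochs$data[, cols, drop = FALSE] == 0
  } else {
    if (is.null(validity)) {
      rlang::abort("`validity` epochs are required unless `literal = TRUE`")
    }
    mat <- validity$data[, cols, drop = FALSE] == 0
  }
  mat[is.na(mat)] <- TRUE
  frac <- rowMeans(mat)
  excl <- frac > zero_frac
  epochs$included <- epochs$included & !excl
  epochs$exclusion_reason <- ifelse(excl & is.na(epochs$exclusion_reason),
                                    "untracked", epochs$exclusion_reason)
  epochs
}

#' Drop epoch pairs in which either member is excluded
#'
#' Paired analyses (classification, blank-matched contrasts) require both
#' the stimulus epoch and its blank to survive exclusion. Marks every
#' epoch whose pair partner is excluded as excluded too, so the included
#' set is a bijection between stimuli and blanks.
#'
#' @param epochs An `epoch_set` containing stimulus and blank epochs.
#' @return The `epoch_set` with a symmetric inclusion mask.
#' @export
harmonise_pairs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep_pair <- tapply(epochs$included, epochs$meta$pair_id, all)
  ok <- as.logical(keep_pair[as.character(epochs$meta$pair_id)])
  newly <- epochs$included & !ok
  epochs$included <- epochs$included & ok
  epochs$exclusion_reason[newly] <- "pair-excluded"
  epochs
}

#' Subset an epoch set by row
#'
#' @param epochs An `epoch_set`.
#' @param idx Logical or integer row index over epochs.
#' @return The subsetted `epoch_set`.
#' @export
subset_epochs <- function(epochs, idx) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs$data <- epochs$data[idx, , drop = FALSE]
  epochs$meta <- epochs$meta[idx, , drop = FALSE]
  epochs$included <- epochs$included[idx]
  epochs$exclusion_reason <- epochs$exclusion_reason[idx]
  epochs
}

#' Mean event-locked trace over included epochs
#'
#' @param epochs An `epoch_set`.
#' @return Tibble with `offset_ms`, `value` (mean over included epochs)
#'   and `sem`.
#' @export
epoch_mean <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- epochs$data[epochs$included, , drop = FALSE]
  if (nrow(d) == 0) rlang::abort("no epochs", class = "oculaware_data_error")
  n <- colSums(!is.na(d))
  tibble::tibble(
    offset_ms = epochs$offsets_ms,
    value = colMeans(d, na.rm = TRUE),
    sem = apply(d, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(1, n))
  )
}

#' Mean fraction timecourse of a binary epoch set
#'
#' Per-sample mean and standard error over the included binary epochs (the
#' proportion of epochs in which the event is present at each offset),
#' with the mean smoothed by a centered moving average.
#'
#' @param epochs Binary `epoch_set` with at least one included epoch.
#' @param smooth_ms Smoothing width in ms.
#' @return A `fraction_trace` tibble (`offset_ms`, `mean`, `sem`) with
#'   attributes `n_epochs` and `kind`.
#' @export
fraction_timecourse <- function(epochs, smooth_ms = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- epochs$data[epochs$included, , drop = FALSE]
  if (nrow(d) == 0) rlang::abort("no epochs", class = "oculaware_data_error")
  m <- colMeans(d, na.rm = TRUE)
  n <- colSums(!is.na(d))
  sem <- apply(d, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(1, n))
  out <- tibble::tibble(
    offset_ms = epochs$offsets_ms,
    mean = moving_average(m, smooth_ms),
    sem = sem
  )
  attr(out, "n_epochs") <- nrow(d)
  attr(out, "kind") <- epochs$kind
  class(out) <- c("fraction_trace", class(out))
  out
}
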