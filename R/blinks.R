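# Blink detection from the pupil trace and pupil cleaning.

#' Blink detection parameters
#'
#' @param velocity_threshold Absolute sample-to-sample pupil change
#'   (recorder units per ms) above which a sample is flagged as a rapid
#'   fluctuation.
#' @param outlier_mad_mult Multiplier on the median absolute deviation for
#'   the outlier-value criterion.
#' @param pad_ms Padding added before and after each flagged interval.
#' @param merge_gap_ms Intervals separated by less than this merge.
#' @return List of class `blink_params`.
#' @export
blink_params <- function(velocity_threshold = 10, outlier_mad_mult = 8,
                         pad_ms = 50, merge_gap_ms = 100) {
  p <- list(velocity_threshold = velocity_threshold,
            outlier_mad_mult = outlier_mad_mult,
            pad_ms = pad_ms, merge_gap_ms = merge_gap_ms)
  for (f in names(p)) {
    if (length(p[[f]]) != 1 || !is.finite(p[[f]]) || p[[f]] <= 0) {
      stop_config(f, "must be a single positive number")
    }
  }
  class(p) <- "blink_params"
  p
}

new_event_timecourse <- function(values, kind, t0 = 0) {
  structure(
    list(values = as.integer(values), kind = kind,
         intervals = runs_to_intervals(values > 0, t0 = t0), t0 = t0),
    class = "event_timecourse"
  )
}

#' @export
print.event_timecourse <- function(x, ...) {
  cat(sprintf("<event_timecourse: %s> %d samples, %d interval(s)\n",
              x$kind, length(x$values), nrow(x$intervals)))
  invisible(x)
}

#' @export
tidy.event_timecourse <- function(x, ...) {
  dplyr::mutate(x$intervals, kind = x$kind, .before = 1)
}

check_recording <- function(recording) {
  stopifnot(all(c("t_ms", "pupil") %in% names(recording)))
  dt <- diff(recording$t_ms)
  if (length(dt) > 0 && (any(dt <= 0) || length(unique(dt)) != 1)) {
    rlang::abort("recording time grid must be strictly increasing with a constant step")
  }
}

#' Detect blinks in a pupil trace
#'
#' A sample falls inside a blink when any of three independent criteria
#' fires: the sample is missing (tracking lost during eye closure), the
#' absolute sample-to-sample pupil change exceeds `velocity_threshold`
#' (the rapid fluctuation of the closing/opening eyelid), or the pupil
#' value deviates from the session median by more than
#' `outlier_mad_mult` x MAD. Flagged runs are padded by `pad_ms` on each
#' side and runs separated by less than `merge_gap_ms` are merged. The
#' result is a binary timecourse (0 = blink absent, 1 = present) with
#' exactly one value per recording sample.
#'
#' @param recording Tibble with at least `t_ms` and `pupil` on a uniform
#'   1-ms grid; `NA` pupil marks lost tracking.
#' @param params A [blink_params()].
#' @return An `event_timecourse` (values + half-open intervals in ms).
#' @export
detect_blinks <- function(recording, params = blink_params()) {
  stopifnot(inherits(params, "blink_params"))
  check_recording(recording)
  p <- recording$pupil
  if (all(is.na(p))) {
    rlang::abort("no valid pupil samples", class = "oculaware_data_error")
  }
  miss <- is.na(p)
  dv <- c(0, abs(diff(p)))
  dv[is.na(dv)] <- 0
  fast <- dv > params$velocity_threshold
  # a large step implicates both samples bracketing the difference
  fast <- fast | c(fast[-1], FALSE)
  med <- stats::median(p, na.rm = TRUE)
  s <- stats::mad(p, na.rm = TRUE)
  outlier <- if (s > 0) abs(p - med) > params$outlier_mad_mult * s else rep(FALSE, length(p))
  outlier[is.na(outlier)] <- FALSE
  flag <- miss | fast | outlier
  flag <- pad_and_merge(flag, params$pad_ms, params$merge_gap_ms)
  new_event_timecourse(flag, kind = "blink", t0 = recording$t_ms[1])
}

#' Clean a pupil trace: interpolate blinks, then smooth
#'
#' Replaces pupil values inside blink intervals (and any remaining missing
#' samples) by linear interpolation between the nearest valid bracketing
#' samples; leading and trailing gaps take the nearest valid value. The
#' interpolated trace is then smoothed with a centered moving average of
#' width `smooth_ms`. Output length equals input length with no missing
#' values.
#'
#' @param recording Tibble with `t_ms` and `pupil`.
#' @param blinks `event_timecourse` from [detect_blinks()], aligned to the
#'   recording.
#' @param smooth_ms Moving-average width in ms (1 = no smoothing).
#' @return The recording tibble with `pupil` replaced by the cleaned trace
#'   and a logical `interpolated` column marking replaced samples.
#' @export
clean_pupil <- function(recording, blinks, smooth_ms = 50) {
  check_recording(recording)
  stopifnot(inherits(blinks, "event_timecourse"))
  if (length(blinks$values) != nrow(recording)) {
    rlang::abort("blink timecourse is not aligned to the recording")
  }
  p <- recording$pupil
  if (all(is.na(p))) {
    rlang::abort("no valid pupil samples", class = "oculaware_data_error")
  }
  mask <- blinks$values > 0 | is.na(p)
  p[mask] <- NA_real_
  p <- zoo::na.approx(p, x = recording$t_ms, na.rm = FALSE, rule = 2)
  out <- recording
  out$pupil <- moving_average(p, smooth_ms)
  out$interpolated <- mask
  out
}
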