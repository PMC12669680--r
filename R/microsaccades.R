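# Median-velocity-threshold microsaccade detection from gaze position.

#' Microsaccade detection parameters
#'
#' Defaults follow the established median-based velocity-threshold
#' detection scheme: a 5-sample moving-window velocity estimate, a
#' threshold of `lambda` = 6 median-based velocity SDs per axis, a minimum
#' event duration of 6 ms, a 1-degree amplitude ceiling (larger events are
#' ordinary saccades) and a 20-ms merge window.
#'
#' @param velocity_window Samples in the centered moving-window velocity
#'   estimate; odd, >= 3.
#' @param lambda Multiplier on the median-based velocity SD.
#' @param min_duration_ms Minimum supra-threshold run length.
#' @param max_amplitude_deg Amplitude ceiling in degrees.
#' @param min_separation_ms Events separated by less than this merge.
#' @return List of class `microsaccade_params`.
#' @export
microsaccade_params <- function(velocity_window = 5, lambda = 6,
                                min_duration_ms = 6, max_amplitude_deg = 1.0,
                                min_separation_ms = 20) {
  p <- list(velocity_window = as.integer(velocity_window), lambda = lambda,
            min_duration_ms = min_duration_ms,
            max_amplitude_deg = max_amplitude_deg,
            min_separation_ms = min_separation_ms)
  if (p$velocity_window < 3 || p$velocity_window %% 2 == 0) {
    stop_config("velocity_window", "must be odd and >= 3")
  }
  if (p$lambda <= 0) stop_config("lambda", "must be > 0")
  if (p$min_duration_ms < 1) stop_config("min_duration_ms", "must be >= 1")
  class(p) <- "microsaccade_params"
  p
}

# Centered moving-window velocity (deg/ms): generalisation of the classic
# 5-sample estimator v_n = (x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / 6.
# Edge samples where the window does not fit are NA (undetectable).
window_velocity <- function(x, window) {
  m <- (window - 1L) %/% 2L
  n <- length(x)
  v <- rep(NA_real_, n)
  if (n < window) return(v)
  core <- (m + 1L):(n - m)
  acc <- numeric(length(core))
  for (k in seq_len(m)) {
    acc <- acc + x[core + k] - x[core - k]
  }
  v[core] <- acc / (2 * sum(seq_len(m)))
  v
}

# Median-based SD estimate: sqrt(median(v^2) - median(v)^2).
median_sd <- function(v) {
  v <- v[!is.na(v)]
  sqrt(max(0, stats::median(v^2) - stats::median(v)^2))
}

#' Detect microsaccades from gaze velocity
#'
#' Computes horizontal and vertical gaze velocities with a centered
#' moving-window estimator, derives per-axis thresholds as `lambda` times
#' the median-based velocity SD, and marks candidate events where the
#' elliptic criterion `(vx/ex)^2 + (vy/ey)^2 > 1` holds for at least
#' `min_duration_ms`. Candidates overlapping excluded (blink) intervals or
#' exceeding the amplitude ceiling are discarded; surviving events closer
#' than `min_separation_ms` are merged. Returns a binary timecourse with
#' one value per recording sample.
#'
#' @param recording Tibble with `t_ms`, `gaze_x`, `gaze_y` on a 1-ms grid.
#' @param params A [microsaccade_params()].
#' @param exclude Optional `event_timecourse` (typically blinks) whose
#'   intervals veto overlapping candidates.
#' @return An `event_timecourse` of kind `"microsaccade"`.
#' @export
detect_microsaccades <- function(recording, params = microsaccade_params(),
                                 exclude = NULL) {
  stopifnot(inherits(params, "microsaccade_params"))
  stopifnot(all(c("t_ms", "gaze_x", "gaze_y") %in% names(recording)))
  n <- nrow(recording)
  if (n < params$velocity_window) {
    rlang::abort("recording shorter than the velocity window",
                 class = "oculaware_data_error")
  }
  vx <- window_velocity(recording$gaze_x, params$velocity_window)
  vy <- window_velocity(recording$gaze_y, params$velocity_window)
  ex <- params$lambda * median_sd(vx)
  ey <- params$lambda * median_sd(vy)
  ratio2 <- function(v, e) {
    out <- rep(0, length(v))
    idx <- !is.na(v)
    if (e > 0) {
      out[idx] <- (v[idx] / e)^2
    } else {
      out[idx] <- ifelse(v[idx] == 0, 0, Inf)
    }
    out
  }
  crit <- ratio2(vx, ex) + ratio2(vy, ey) > 1
  iv <- runs_to_intervals(crit, t0 = recording$t_ms[1])
  if (nrow(iv) > 0) {
    iv <- iv[iv$end_ms - iv$start_ms >= params$min_duration_ms, , drop = FALSE]
  }
  # veto: overlap with excluded intervals
  if (!is.null(exclude) && nrow(iv) > 0 && nrow(exclude$intervals) > 0) {
    keep <- vapply(seq_len(nrow(iv)), function(i) {
      !any(iv$start_ms[i] < exclude$intervals$end_ms &
           iv$end_ms[i] > exclude$intervals$start_ms)
    }, logical(1))
    iv <- iv[keep, , drop = FALSE]
  }
  # amplitude ceiling (peak-to-peak displacement within the event)
  if (nrow(iv) > 0) {
    t0 <- recording$t_ms[1]
    keep <- vapply(seq_len(nrow(iv)), function(i) {
      a <- iv$start_ms[i] - t0 + 1
      b <- iv$end_ms[i] - t0
      gx <- recording$gaze_x[a:b]; gy <- recording$gaze_y[a:b]
      amp <- sqrt(diff(range(gx))^2 + diff(range(gy))^2)
      amp <= params$max_amplitude_deg
    }, logical(1))
    iv <- iv[keep, , drop = FALSE]
  }
  # merge events separated by less than min_separation_ms
  if (nrow(iv) > 1) {
    merged <- iv[1, ]
    for (i in 2:nrow(iv)) {
      if (iv$start_ms[i] - merged$end_ms[nrow(merged)] < params$min_separation_ms) {
        merged$end_ms[nrow(merged)] <- iv$end_ms[i]
      } else {
        merged <- rbind(merged, iv[i, ])
      }
    }
    iv <- merged
  }
  flag <- intervals_to_flag(iv, n, t0 = recording$t_ms[1])
  new_event_timecourse(flag, kind = "microsaccade", t0 = recording$t_ms[1])
}
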