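# Shared fixtures and independent oracles, built in code at test time.

# A small, quick session configuration; override fields as needed.
quick_config <- function(..., n_blocks = 1, trials_per_block = 10, seed = 11) {
  synth_config(n_blocks = n_blocks, trials_per_block = trials_per_block,
               seed = seed, ...)
}

# Flat recording tibble on the 1-ms grid.
flat_recording <- function(n_ms, pupil = 1000, gx = 0, gy = 0) {
  tibble::tibble(
    t_ms = seq_len(n_ms) - 1L,
    pupil = rep(pupil, length.out = n_ms),
    gaze_x = rep(gx, length.out = n_ms),
    gaze_y = rep(gy, length.out = n_ms),
    valid = TRUE
  )
}

# Independent brute-force microsaccade reference: explicit loops, no
# vectorised run scanning, mirroring the published median-velocity-threshold
# definition directly.
brute_force_microsaccades <- function(recording, params, exclude = NULL) {
  x <- recording$gaze_x
  y <- recording$gaze_y
  n <- length(x)
  m <- (params$velocity_window - 1) / 2
  vx <- rep(NA_real_, n)
  vy <- rep(NA_real_, n)
  for (i in (m + 1):(n - m)) {
    sx <- 0
    sy <- 0
    for (k in 1:m) {
      sx <- sx + x[i + k] - x[i - k]
      sy <- sy + y[i + k] - y[i - k]
    }
    vx[i] <- sx / (2 * sum(1:m))
    vy[i] <- sy / (2 * sum(1:m))
  }
  msd <- function(v) {
    v <- v[!is.na(v)]
    sqrt(max(0, median(v^2) - median(v)^2))
  }
  ex <- params$lambda * msd(vx)
  ey <- params$lambda * msd(vy)
  crit <- logical(n)
  for (i in 1:n) {
    if (is.na(vx[i])) next
    rx <- if (ex > 0) (vx[i] / ex)^2 else if (vx[i] == 0) 0 else Inf
    ry <- if (ey > 0) (vy[i] / ey)^2 else if (vy[i] == 0) 0 else Inf
    crit[i] <- rx + ry > 1
  }
  # run scan
  t0 <- recording$t_ms[1]
  iv <- list()
  i <- 1
  while (i <= n) {
    if (crit[i]) {
      j <- i
      while (j < n && crit[j + 1]) j <- j + 1
      if (j - i + 1 >= params$min_duration_ms) {
        iv[[length(iv) + 1]] <- c(t0 + i - 1, t0 + j)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  keep <- list()
  for (e in iv) {
    a <- e[1] - t0 + 1
    b <- e[2] - t0
    vetoed <- FALSE
    if (!is.null(exclude)) {
      for (r in seq_len(nrow(exclude$intervals))) {
        if (e[1] < exclude$intervals$end_ms[r] &&
            e[2] > exclude$intervals$start_ms[r]) {
          vetoed <- TRUE
        }
      }
    }
    amp <- sqrt(diff(range(x[a:b]))^2 + diff(range(y[a:b]))^2)
    if (!vetoed && amp <= params$max_amplitude_deg) {
      keep[[length(keep) + 1]] <- e
    }
  }
  merged <- list()
  for (e in keep) {
    if (length(merged) > 0 &&
        e[1] - merged[[length(merged)]][2] < params$min_separation_ms) {
      merged[[length(merged)]][2] <- e[2]
    } else {
      merged[[length(merged) + 1]] <- e
    }
  }
  if (length(merged) == 0) {
    return(tibble::tibble(start_ms = numeric(0), end_ms = numeric(0)))
  }
  tibble::tibble(
    start_ms = vapply(merged, `[`, numeric(1), 1),
    end_ms = vapply(merged, `[`, numeric(1), 2)
  )
}

# Gaze with well-separated injected events of detectable duration.
injected_gaze <- function(n_events = 50, spacing_ms = 600, noise_sd = 0.01,
                          dur_range = c(8, 12), amp_range = c(0.2, 0.8),
                          seed = 1) {
  set.seed(seed)
  onsets <- 200 + (seq_len(n_events) - 1) * spacing_ms
  ev <- tibble::tibble(
    onset_ms = onsets,
    duration_ms = round(runif(n_events, dur_range[1], dur_range[2])),
    amplitude_deg = runif(n_events, amp_range[1], amp_range[2])
  )
  g <- simulate_gaze(max(onsets) + 400, ev, noise_sd = noise_sd)
  g$pupil <- 1000
  g$valid <- TRUE
  list(recording = g, truth = ev)
}

# Count injected events whose interval overlaps a detected interval.
overlap_hits <- function(truth_onset, truth_end, intervals) {
  vapply(seq_along(truth_onset), function(i) {
    any(intervals$start_ms < truth_end[i] & intervals$end_ms > truth_onset[i])
  }, logical(1))
}
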