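# Synthetic session generator: a monocular 1000-Hz pupil + gaze recording
# with stimulus-evoked structure, blink dropouts, microsaccades, and the
# behavioural response log that goes with it.

# Unimodal pupil response kernel (gamma-family impulse response widely used
# for event-locked pupillometry), normalised to peak 1. t in ms.
dilation_kernel <- function(t_ms, t_max = 930, shape = 10.1) {
  k <- numeric(length(t_ms))
  pos <- t_ms > 0
  tt <- t_ms[pos]
  k[pos] <- (tt / t_max)^shape * exp(shape * (1 - tt / t_max))
  k
}

# Sustained constriction kernel: raised-cosine onset ramp, unit plateau for
# the stimulus duration, exponential recovery after offset. Peak -1 scaled
# by a (negative) amplitude gives the familiar light-response trough.
constriction_kernel <- function(t_ms, stim_ms = 3000, rise_ms = 600,
                                decay_tau_ms = 1000) {
  k <- numeric(length(t_ms))
  rise <- t_ms > 0 & t_ms <= rise_ms
  k[rise] <- (1 - cos(pi * t_ms[rise] / rise_ms)) / 2
  hold <- t_ms > rise_ms & t_ms <= stim_ms
  k[hold] <- 1
  fall <- t_ms > stim_ms
  k[fall] <- exp(-(t_ms[fall] - stim_ms) / decay_tau_ms)
  k
}

target_classes <- c("target-plus", "target-x")
nontarget_classes <- c("white", "glare", "nonglare", "isoluminant")

# Event-locked rate multiplier vector for an inhomogeneous point process:
# piecewise-constant windows [0, 500) ms after stimulus onset and offset.
modulation_vector <- function(n, onsets, stim_ms, mult, window_ms = 500) {
  mod <- rep(1, n)
  for (on in onsets) {
    a <- on + 1; b <- min(n, on + window_ms)
    if (a <= b) mod[a:b] <- mod[a:b] * mult[["onset"]]
    a2 <- on + stim_ms + 1; b2 <- min(n, on + stim_ms + window_ms)
    if (a2 <= b2) mod[a2:b2] <- mod[a2:b2] * mult[["offset"]]
  }
  mod
}

#' Simulate fixational gaze with embedded microsaccades
#'
#' Produces horizontal/vertical gaze position (degrees of visual angle) on a
#' 1-ms grid: slow AR(1) fixation drift plus white jitter, with each
#' microsaccade realised as a conjugate raised-cosine step displacement of
#' known onset, duration and amplitude. Used internally by
#' [generate_session()] and directly by detector validation, where the event
#' table is the ground truth.
#'
#' @param n_ms Recording length in ms.
#' @param events Tibble with `onset_ms`, `duration_ms`, `amplitude_deg` and
#'   optionally `direction_rad` (drawn to re-centre gaze when absent).
#' @param noise_sd White jitter SD, degrees.
#' @param drift_sd AR(1) drift innovation SD, degrees.
#' @param drift_coef AR(1) drift coefficient.
#' @return Tibble with `t_ms`, `gaze_x`, `gaze_y`.
#' @export
simulate_gaze <- function(n_ms, events = NULL, noise_sd = 0.01,
                          drift_sd = 0.0002, drift_coef = 0.999) {
  drift_x <- as.numeric(stats::filter(stats::rnorm(n_ms, 0, drift_sd),
                                      drift_coef, method = "recursive"))
  drift_y <- as.numeric(stats::filter(stats::rnorm(n_ms, 0, drift_sd),
                                      drift_coef, method = "recursive"))
  x <- drift_x
  y <- drift_y
  if (!is.null(events) && nrow(events) > 0) {
    events <- dplyr::arrange(events, .data$onset_ms)
    cum_x <- 0; cum_y <- 0
    # per-sample displacement increments; the persistent step positions are
    # recovered by one cumulative sum at the end
    dx <- numeric(n_ms); dy <- numeric(n_ms)
    for (i in seq_len(nrow(events))) {
      on <- events$onset_ms[i]
      dur <- events$duration_ms[i]
      amp <- events$amplitude_deg[i]
      if ("direction_rad" %in% names(events)) {
        th <- events$direction_rad[i]
      } else if (sqrt(cum_x^2 + cum_y^2) > 0.3) {
        # bias back toward fixation so position stays bounded (square-wave-
        # jerk-like behaviour)
        th <- atan2(-cum_y, -cum_x) + stats::rnorm(1, 0, 0.5)
      } else {
        th <- stats::runif(1, 0, 2 * pi)
      }
      a <- on + 1
      if (a > n_ms) next
      b <- min(n_ms, on + dur)
      u <- seq_len(b - a + 1)
      prof <- amp * (1 - cos(pi * u / dur)) / 2
      inc <- diff(c(0, prof))
      dx[a:b] <- dx[a:b] + cos(th) * inc
      dy[a:b] <- dy[a:b] + sin(th) * inc
      cum_x <- cum_x + cos(th) * amp
      cum_y <- cum_y + sin(th) * amp
    }
    x <- x + cumsum(dx)
    y <- y + cumsum(dy)
  }
  tibble::tibble(
    t_ms = seq_len(n_ms) - 1L,
    gaze_x = x + stats::rnorm(n_ms, 0, noise_sd),
    gaze_y = y + stats::rnorm(n_ms, 0, noise_sd)
  )
}

# Draw event onsets of an inhomogeneous point process by per-ms thinning.
draw_point_process <- function(n_ms, base_rate_hz, mod) {
  p <- pmin(1, base_rate_hz / 1000 * mod)
  which(stats::runif(n_ms) < p) - 1L
}

#' Generate a synthetic eye-tracking session
#'
#' Simulates one full task session under a [synth_config()]: the event log
#' (stimulus class, presentation field, block), the raw 1000-Hz recording
#' (pupil with blink dropouts and ramp artifacts, gaze with microsaccades),
#' and the behavioural response log (keypresses for perceived targets).
#' The pupil trace is baseline + summed evoked kernels (dilation for
#' targets, class-scaled sustained constriction for nontargets, both scaled
#' by the per-field gain) + AR(1) and white noise. Blinks and microsaccades
#' are inhomogeneous point processes whose rates are the base rates times
#' the piecewise-constant onset/offset modulation profiles.
#'
#' All randomness derives from `config$seed` via named substreams, so a
#' fixed config reproduces the session exactly.
#'
#' @param config A [synth_config()].
#' @return A list of class `eye_session` with elements `recording`
#'   (tibble: `t_ms`, `pupil`, `gaze_x`, `gaze_y`, `valid`), `events`
#'   (tibble: `onset_ms`, `event_class`, `field`, `block`, `event_id`),
#'   `responses` (tibble: `press_ms`, `key`), `block_end_ms`, `config`, and
#'   `truth` (injected blink intervals and microsaccade events, for
#'   validation against ground truth).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  seeds <- substream_seeds(config$seed,
                           c("events", "pupil", "blinks", "microsaccades",
                             "gaze", "responses"))

  ## -- event log ------------------------------------------------------
  set.seed(seeds[["events"]])
  stim_ms <- round(config$stim_duration * 1000)
  n_trials <- config$n_blocks * config$trials_per_block
  classes <- sample(names(config$stimulus_mix), n_trials, replace = TRUE,
                    prob = config$stimulus_mix)
  fields <- sample(names(config$field_mix), n_trials, replace = TRUE,
                   prob = config$field_mix)
  pre <- stats::runif(n_trials, config$pre_stim_jitter[1], config$pre_stim_jitter[2])
  post <- stats::runif(n_trials, config$post_stim_jitter[1], config$post_stim_jitter[2])
  onset <- integer(n_trials)
  block <- rep(seq_len(config$n_blocks), each = config$trials_per_block)
  block_end_ms <- numeric(config$n_blocks)
  t_cursor <- 0
  for (i in seq_len(n_trials)) {
    t_cursor <- t_cursor + round(pre[i] * 1000)
    onset[i] <- t_cursor
    t_cursor <- t_cursor + stim_ms + round(post[i] * 1000)
    if (i %% config$trials_per_block == 0) {
      block_end_ms[block[i]] <- t_cursor
    }
  }
  n_ms <- t_cursor
  events <- tibble::tibble(
    onset_ms = onset, event_class = classes, field = fields,
    block = block, event_id = seq_len(n_trials), is_blank = FALSE
  )

  ## -- pupil trace ----------------------------------------------------
  set.seed(seeds[["pupil"]])
  ar <- as.numeric(stats::filter(stats::rnorm(n_ms, 0, config$noise_sd),
                                 config$ar_coef, method = "recursive"))
  pupil <- config$pupil_baseline + ar + stats::rnorm(n_ms, 0, config$noise_sd / 4)
  gains <- config$evoked_gain_by_field
  span <- stim_ms + 4000
  for (i in seq_len(n_trials)) {
    g <- gains[[fields[i]]]
    if (g == 0) next
    lat <- round(config$response_latency * 1000)
    a <- onset[i] + lat + 1
    b <- min(n_ms, onset[i] + lat + span)
    if (a > n_ms) next
    rel <- seq_len(b - a + 1)
    if (classes[i] %in% target_classes) {
      amp <- config$dilation_amp * g
      if (amp != 0) pupil[a:b] <- pupil[a:b] + amp * dilation_kernel(rel)
    } else {
      amp <- config$constriction_amp_by_class[[classes[i]]] * g
      if (amp != 0) {
        pupil[a:b] <- pupil[a:b] + amp * constriction_kernel(rel, stim_ms = stim_ms)
      }
    }
  }

  ## -- blinks ---------------------------------------------------------
  set.seed(seeds[["blinks"]])
  blink_mod <- modulation_vector(n_ms, onset, stim_ms,
                                 config$modulation_profiles$blink)
  blink_on <- draw_point_process(n_ms, config$blink_base_rate, blink_mod)
  blink_dur <- round(1000 * stats::rlnorm(length(blink_on),
                                          config$blink_duration_meanlog,
                                          config$blink_duration_sdlog))
  # drop blinks that would start inside a previous one
  keep <- rep(TRUE, length(blink_on))
  last_end <- -Inf
  for (i in seq_along(blink_on)) {
    if (blink_on[i] < last_end + config$blink_ramp_ms) {
      keep[i] <- FALSE
    } else {
      last_end <- blink_on[i] + blink_dur[i]
    }
  }
  blink_on <- blink_on[keep]; blink_dur <- blink_dur[keep]
  valid <- rep(TRUE, n_ms)
  ramp <- config$blink_ramp_ms
  for (i in seq_along(blink_on)) {
    a <- blink_on[i] + 1
    b <- min(n_ms, blink_on[i] + blink_dur[i])
    if (a > n_ms) next
    # steep closing/opening ramps flanking the dropout
    ra <- max(1, a - ramp):(a - 1)
    if (length(ra) > 0 && a > 1) {
      pupil[ra] <- pupil[ra] -
        config$blink_ramp_drop * seq_along(ra) / length(ra)
    }
    if (b < n_ms) {
      rb <- (b + 1):min(n_ms, b + ramp)
      pupil[rb] <- pupil[rb] -
        config$blink_ramp_drop * rev(seq_along(rb)) / length(rb)
    }
    pupil[a:b] <- NA_real_
    valid[a:b] <- FALSE
  }
  blink_truth <- tibble::tibble(
    start_ms = blink_on,
    end_ms = pmin(n_ms, blink_on + blink_dur)
  )

  ## -- microsaccades + gaze ------------------------------------------
  set.seed(seeds[["microsaccades"]])
  ms_mod <- modulation_vector(n_ms, onset, stim_ms,
                              config$modulation_profiles$microsaccade)
  ms_on <- draw_point_process(n_ms, config$microsaccade_base_rate, ms_mod)
  # enforce a refractory gap so injected events stay separable
  if (length(ms_on) > 1) {
    ms_on <- ms_on[c(TRUE, diff(ms_on) > 50)]
  }
  ms_truth <- tibble::tibble(
    onset_ms = ms_on,
    duration_ms = round(stats::runif(length(ms_on),
                                     config$ms_duration_range[1],
                                     config$ms_duration_range[2])),
    amplitude_deg = stats::runif(length(ms_on),
                                 config$ms_amp_range[1],
                                 config$ms_amp_range[2])
  )
  set.seed(seeds[["gaze"]])
  gaze <- simulate_gaze(n_ms, ms_truth,
                        noise_sd = config$gaze_noise_sd,
                        drift_sd = config$gaze_drift_sd)

  ## -- responses ------------------------------------------------------
  set.seed(seeds[["responses"]])
  is_target <- classes %in% target_classes
  perc_p <- config$perception_prob_by_field[fields]
  perceived <- is_target & (stats::runif(n_trials) < perc_p)
  idx <- which(perceived)
  press_ms <- onset[idx] + round(1000 * rnorm_pos(length(idx),
                                                  config$rt_mean, config$rt_sd))
  correct <- stats::runif(length(idx)) < config$orientation_accuracy
  true_key <- ifelse(classes[idx] == "target-plus", "plus", "x")
  key <- ifelse(correct, true_key, ifelse(true_key == "plus", "x", "plus"))
  ord <- order(press_ms)
  press_ms <- press_ms[ord]; key <- key[ord]
  # enforce strictly increasing press times
  if (length(press_ms) > 1) {
    for (i in 2:length(press_ms)) {
      if (press_ms[i] <= press_ms[i - 1]) press_ms[i] <- press_ms[i - 1] + 1
    }
  }
  responses <- tibble::tibble(press_ms = press_ms, key = key)

  structure(
    list(
      recording = tibble::tibble(
        t_ms = seq_len(n_ms) - 1L,
        pupil = pupil,
        gaze_x = gaze$gaze_x,
        gaze_y = gaze$gaze_y,
        valid = valid
      ),
      events = events,
      responses = responses,
      block_end_ms = block_end_ms,
      config = config,
      truth = list(blinks = blink_truth, microsaccades = ms_truth,
                   perceived = perceived)
    ),
    class = "eye_session"
  )
}

#' @export
print.eye_session <- function(x, ...) {
  cat("<eye_session>\n")
  cat(sprintf("  %.1f min recording, %d events, %d responses\n",
              nrow(x$recording) / 60000, nrow(x$events), nrow(x$responses)))
  cat(sprintf("  injected: %d blinks, %d microsaccades\n",
              nrow(x$truth$blinks), nrow(x$truth$microsaccades)))
  invisible(x)
}
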