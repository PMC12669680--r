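#' Configuration for the synthetic eye-tracking session generator
#'
#' Builds and validates the parameter set that [generate_session()] uses to
#' emulate a monocular 1000-Hz recording of a peripheral visual detection
#' task: jittered 3-5 s fixation, 3 s stimulus, jittered 3-5 s post-stimulus
#' response period, with target stimuli evoking pupil dilation and the
#' luminance-graded nontargets evoking sustained constriction.
#'
#' Amplitudes are in recorder units (pixels, as reported by a video-based
#' eye tracker); rates in events per second; durations and latencies in
#' seconds. `evoked_gain_by_field` scales every evoked kernel per
#' presentation field, so a fully unresponsive blind field is
#' `c(sighted = 1, blind = 0)` and a reduced-amplitude responsive blind
#' field (the default) is `c(sighted = 1, blind = 0.4)`.
#'
#' @param sampling_rate Samples per second; the generator assumes 1000.
#' @param n_blocks,trials_per_block Task block structure.
#' @param pre_stim_jitter,post_stim_jitter Length-2 jitter intervals in s.
#' @param stim_duration Stimulus presentation duration in s.
#' @param stimulus_mix Named proportions over the six stimulus classes.
#' @param field_mix Named proportions over the two presentation fields.
#' @param pupil_baseline Baseline pupil size, recorder units.
#' @param dilation_amp Target-evoked dilation amplitude, recorder units.
#' @param constriction_amp_by_class Named signed constriction amplitudes
#'   (recorder units) for the four nontarget classes.
#' @param evoked_gain_by_field Named per-field multiplier on evoked kernels.
#' @param response_latency Evoked-kernel onset latency in s.
#' @param blink_base_rate,microsaccade_base_rate Baseline event rates, 1/s.
#' @param modulation_profiles List with elements `blink` and `microsaccade`,
#'   each a named vector `c(onset = , offset = )` of rate multipliers applied
#'   in the 500-ms windows starting at stimulus onset and offset.
#' @param perception_prob_by_field Named per-field probability that a target
#'   is consciously perceived (and answered).
#' @param rt_mean,rt_sd Keypress latency distribution in s (normal,
#'   truncated at zero).
#' @param orientation_accuracy Probability that a perceived target's
#'   orientation key is correct.
#' @param noise_sd Innovation SD of the AR(1) pupil noise; a white
#'   measurement noise component of SD `noise_sd / 4` is added on top.
#' @param ar_coef AR(1) coefficient of the pupil noise.
#' @param blink_duration_meanlog,blink_duration_sdlog Lognormal blink
#'   duration parameters (seconds; the defaults give a 150-ms median).
#' @param blink_ramp_ms,blink_ramp_drop Width (ms) and depth (recorder
#'   units) of the steep artifactual ramps flanking each blink dropout.
#' @param ms_amp_range,ms_duration_range Microsaccade amplitude (degrees)
#'   and displacement duration (ms) ranges.
#' @param gaze_noise_sd White fixation jitter SD, degrees per sample.
#' @param gaze_drift_sd Innovation SD of the slow AR(1) fixation drift.
#' @param seed Master seed; expanded into per-component substreams.
#' @return A validated list of class `synth_config`.
#' @seealso [generate_session()]
#' @export
synth_config <- function(sampling_rate = 1000,
                         n_blocks = 10,
                         trials_per_block = 40,
                         pre_stim_jitter = c(3, 5),
                         stim_duration = 3,
                         post_stim_jitter = c(3, 5),
                         stimulus_mix = c(
                           "target-plus" = 0.1, "target-x" = 0.1,
                           "white" = 0.2, "glare" = 0.2,
                           "nonglare" = 0.2, "isoluminant" = 0.2
                         ),
                         field_mix = c(sighted = 0.5, blind = 0.5),
                         pupil_baseline = 1000,
                         dilation_amp = 60,
                         constriction_amp_by_class = c(
                           white = -120, glare = -80,
                           nonglare = -40, isoluminant = -10
                         ),
                         evoked_gain_by_field = c(sighted = 1, blind = 0.4),
                         response_latency = 0.25,
                         blink_base_rate = 0.25,
                         microsaccade_base_rate = 1.5,
                         modulation_profiles = list(
                           blink = c(onset = 0.3, offset = 2.0),
                           microsaccade = c(onset = 0.2, offset = 0.5)
                         ),
                         perception_prob_by_field = c(sighted = 0.95, blind = 0.05),
                         rt_mean = 0.9,
                         rt_sd = 0.3,
                         orientation_accuracy = 0.9,
                         noise_sd = 1.5,
                         ar_coef = 0.99,
                         blink_duration_meanlog = log(0.150),
                         blink_duration_sdlog = 0.4,
                         blink_ramp_ms = 30,
                         blink_ramp_drop = 600,
                         ms_amp_range = c(0.1, 1.0),
                         ms_duration_range = c(2, 12),
                         gaze_noise_sd = 0.01,
                         gaze_drift_sd = 0.0002,
                         seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  check_mix <- function(x, field) {
    if (is.null(names(x)) || any(names(x) == "")) {
      stop_config(field, "must be a fully named proportion vector")
    }
    if (any(x < 0)) stop_config(field, "proportions must be nonnegative")
    if (abs(sum(x) - 1) > 1e-6) stop_config(field, "proportions must sum to 1")
  }
  check_mix(cfg$stimulus_mix, "stimulus_mix")
  check_mix(cfg$field_mix, "field_mix")
  if (any(cfg$perception_prob_by_field < 0 | cfg$perception_prob_by_field > 1)) {
    stop_config("perception_prob_by_field", "probabilities must lie in [0, 1]")
  }
  if (!setequal(names(cfg$perception_prob_by_field), names(cfg$field_mix))) {
    stop_config("perception_prob_by_field", "fields must match field_mix")
  }
  if (!setequal(names(cfg$evoked_gain_by_field), names(cfg$field_mix))) {
    stop_config("evoked_gain_by_field", "fields must match field_mix")
  }
  for (f in c("n_blocks", "trials_per_block", "stim_duration", "pupil_baseline",
              "blink_base_rate", "microsaccade_base_rate", "rt_mean", "rt_sd",
              "noise_sd", "response_latency", "blink_ramp_ms", "blink_ramp_drop")) {
    if (length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) || cfg[[f]] < 0) {
      stop_config(f, "must be a single nonnegative number")
    }
  }
  if (cfg$sampling_rate != 1000) {
    stop_config("sampling_rate", "the generator emulates a 1000-Hz recorder")
  }
  for (f in c("pre_stim_jitter", "post_stim_jitter", "ms_amp_range",
              "ms_duration_range")) {
    x <- cfg[[f]]
    if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2] || any(x < 0)) {
      stop_config(f, "must be a nonnegative interval c(lower, upper)")
    }
  }
  for (m in c("blink", "microsaccade")) {
    prof <- cfg$modulation_profiles[[m]]
    if (is.null(prof) || !all(c("onset", "offset") %in% names(prof)) ||
        any(prof < 0)) {
      stop_config("modulation_profiles",
                  sprintf("`%s` needs nonnegative c(onset, offset) multipliers", m))
    }
  }
  unknown <- setdiff(names(cfg$constriction_amp_by_class),
                     c("white", "glare", "nonglare", "isoluminant"))
  if (length(unknown) > 0) {
    stop_config("constriction_amp_by_class",
                paste("unknown stimulus class:", paste(unknown, collapse = ", ")))
  }
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d block(s) x %d trials, %.0f Hz\n",
              x$n_blocks, x$trials_per_block, x$sampling_rate))
  cat(sprintf("  fields: %s\n",
              paste(sprintf("%s=%.2f", names(x$field_mix), x$field_mix),
                    collapse = ", ")))
  cat(sprintf("  dilation %.0f, constriction %s (units)\n", x$dilation_amp,
              paste(sprintf("%s %.0f", names(x$constriction_amp_by_class),
                            x$constriction_amp_by_class), collapse = ", ")))
  cat(sprintf("  blink %.2f/s, microsaccade %.2f/s, seed %d\n",
              x$blink_base_rate, x$microsaccade_base_rate, x$seed))
  invisible(x)
}
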