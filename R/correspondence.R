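# Present/absent designation across the three blind-field measures.

#' Correspondence table across task behaviour, verbal report and eye metrics
#'
#' Applies the predetermined presence criteria per participant:
#' task behaviour is *present* when the blind-field target perception rate
#' is strictly greater than 0.25; verbal report is *present* when conscious
#' awareness was reported for strictly more than 10% of task stimuli; eye
#' metrics are *present* when at least one stimulus-evoked eye-metric
#' response is present (e.g. the [eye_metric_presence()] criterion, or a
#' manual designation).
#'
#' @param data Tibble with one row per participant: `participant`,
#'   `perception_rate` (blind field), `verbal_fraction`, `eye_present`
#'   (logical).
#' @param rate_threshold,verbal_threshold Presence cutoffs (strict).
#' @return Tibble with `participant`, `task_behavior`, `verbal_report`,
#'   `eye_metrics` (each `"present"`/`"absent"`) and `agree` (all three
#'   measures agree); attribute `"n_agree"` counts agreeing participants.
#' @export
correspondence_table <- function(data, rate_threshold = 0.25,
                                 verbal_threshold = 0.10) {
  stopifnot(all(c("participant", "perception_rate", "verbal_fraction",
                  "eye_present") %in% names(data)))
  pa <- function(x) ifelse(x, "present", "absent")
  out <- tibble::tibble(
    participant = data$participant,
    task_behavior = pa(data$perception_rate > rate_threshold),
    verbal_report = pa(data$verbal_fraction > verbal_threshold),
    eye_metrics = pa(as.logical(data$eye_present))
  )
  out$agree <- out$task_behavior == out$verbal_report &
    out$verbal_report == out$eye_metrics
  attr(out, "n_agree") <- sum(out$agree)
  out
}
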