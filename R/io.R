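# Plain-text serialization of synthetic sessions.

#' Write a session to a directory of plain-text files
#'
#' Sample log as tab-separated text (`t_ms`, `pupil`, `gaze_x`, `gaze_y`,
#' `valid`), event and response logs as headed CSV, and a YAML sidecar
#' echoing the generating configuration and block end times.
#'
#' @param session An `eye_session` from [generate_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "eye_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- session$recording
  rec$valid <- as.integer(rec$valid)
  utils::write.table(rec, file.path(dir, "samples.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(session$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(session$responses, file.path(dir, "responses.csv"),
                   row.names = FALSE)
  cfg <- unclass(session$config)
  cfg$modulation_profiles <- lapply(cfg$modulation_profiles, as.list)
  yaml::write_yaml(list(config = cfg,
                        block_end_ms = as.numeric(session$block_end_ms)),
                   file.path(dir, "session.yml"))
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir Directory containing `samples.tsv`, `events.csv`,
#'   `responses.csv`, `session.yml`.
#' @return List with `recording`, `events`, `responses`, `block_end_ms`,
#'   `config` (plain list echo).
#' @export
read_session <- function(dir) {
  rec <- utils::read.delim(file.path(dir, "samples.tsv"))
  rec$valid <- rec$valid == 1
  side <- yaml::read_yaml(file.path(dir, "session.yml"))
  responses <- utils::read.csv(
    file.path(dir, "responses.csv"),
    colClasses = c(press_ms = "numeric", key = "character")
  )
  list(
    recording = tibble::as_tibble(rec),
    events = tibble::as_tibble(utils::read.csv(file.path(dir, "events.csv"))),
    responses = tibble::as_tibble(responses),
    block_end_ms = side$block_end_ms,
    config = side$config
  )
}
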