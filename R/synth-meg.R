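# Synthetic evoked field potentials for a single posterior sensor.

# Evoked waveform on an offset grid (ms): P1 bump near 100 ms, N2 trough in
# 100-225 ms, sustained late negativity after 250 ms. Amplitudes in fT;
# N2/LN amplitudes are magnitudes of the negative deflections.
evoked_field_waveform <- function(offsets_ms, amps) {
  p1 <- amps[["P1"]] * exp(-((offsets_ms - 100)^2) / (2 * 15^2))
  n2 <- -amps[["N2"]] * exp(-((offsets_ms - 165)^2) / (2 * 30^2))
  ln <- numeric(length(offsets_ms))
  ramp <- offsets_ms > 250 & offsets_ms <= 350
  ln[ramp] <- (offsets_ms[ramp] - 250) / 100
  hold <- offsets_ms > 350 & offsets_ms <= 900
  ln[hold] <- 1
  fall <- offsets_ms > 900
  ln[fall] <- exp(-(offsets_ms[fall] - 900) / 400)
  p1 + n2 - amps[["LN"]] * ln
}

#' Generate synthetic evoked field-potential epochs
#'
#' Builds per-condition epochs on a symmetric offset grid (default -4000 to
#' +4000 ms, 8001 samples at 1000 Hz) with an evoked waveform composed of a
#' P1 positivity near 100 ms, an N2 trough between 100 and 225 ms and a
#' sustained late negativity after 250 ms, scaled per condition, plus white
#' Gaussian sensor noise.
#'
#' @param n_per_condition Epochs per condition (>= 2).
#' @param component_amps Named list: one element per condition, each a named
#'   vector `c(P1 = , N2 = , LN = )` of component amplitudes in fT (N2 and
#'   LN as positive magnitudes of negative deflections).
#' @param noise_sd Gaussian sensor noise SD, fT.
#' @param seed Seed.
#' @param half_window_ms Half-width of the epoch grid in ms.
#' @param sampling_rate Samples per second of the grid.
#' @return An `fp_epochs` object: list with `data` (epochs x samples, fT),
#'   `offsets_ms`, `condition` (factor per epoch) and `sampling_rate`.
#' @export
generate_field_potential_epochs <- function(n_per_condition, component_amps,
                                            noise_sd = 30, seed = 1,
                                            half_window_ms = 4000,
                                            sampling_rate = 1000) {
  stopifnot(n_per_condition >= 2, length(component_amps) >= 1)
  for (cond in names(component_amps)) {
    a <- component_amps[[cond]]
    if (!all(c("P1", "N2", "LN") %in% names(a))) {
      stop_config("component_amps",
                  sprintf("condition `%s` needs c(P1, N2, LN)", cond))
    }
  }
  set.seed(as.integer(seed))
  step <- 1000 / sampling_rate
  offsets_ms <- seq(-half_window_ms, half_window_ms, by = step)
  n_s <- length(offsets_ms)
  conds <- names(component_amps)
  data <- matrix(0, nrow = n_per_condition * length(conds), ncol = n_s)
  condition <- character(nrow(data))
  row <- 1L
  for (cond in conds) {
    wave <- evoked_field_waveform(offsets_ms, component_amps[[cond]])
    for (i in seq_len(n_per_condition)) {
      data[row, ] <- wave + stats::rnorm(n_s, 0, noise_sd)
      condition[row] <- cond
      row <- row + 1L
    }
  }
  structure(
    list(data = data, offsets_ms = offsets_ms,
         condition = factor(condition, levels = conds),
         sampling_rate = sampling_rate),
    class = "fp_epochs"
  )
}

#' @export
print.fp_epochs <- function(x, ...) {
  cat("<fp_epochs>\n")
  tab <- table(x$condition)
  cat(sprintf("  %d epochs x %d samples (%.0f Hz), offsets %g..%g ms\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              min(x$offsets_ms), max(x$offsets_ms)))
  cat("  conditions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.fp_epochs <- function(x, ...) {
  tibble::tibble(
    epoch = rep(seq_len(nrow(x$data)), each = ncol(x$data)),
    condition = rep(as.character(x$condition), each = ncol(x$data)),
    offset_ms = rep(x$offsets_ms, nrow(x$data)),
    value = as.vector(t(x$data))
  )
}
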