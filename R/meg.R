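# Single-sensor field-potential preprocessing, epoching and cluster-based
# permutation statistics.

#' Band-pass and notch filter a sensor trace
#'
#' Zero-phase (forward-backward Butterworth) band-pass between `band[1]`
#' and `band[2]` Hz plus a narrow zero-phase band-stop at each line
#' frequency in `notches`. Sample count is preserved. Notches at or above
#' the Nyquist frequency are skipped.
#'
#' @param x Numeric sensor trace (fT).
#' @param sampling_rate Samples per second; must exceed twice `band[2]`.
#' @param band Pass band in Hz.
#' @param notches Line frequencies to remove, Hz.
#' @param notch_halfwidth_hz Half-width of each band-stop, Hz.
#' @return Filtered numeric vector, same length as `x`.
#' @export
preprocess_field <- function(x, sampling_rate, band = c(0.1, 115),
                             notches = c(60, 120), notch_halfwidth_hz = 2) {
  stopifnot(is.numeric(x), length(band) == 2, band[1] < band[2])
  nyq <- sampling_rate / 2
  if (band[2] >= nyq) {
    rlang::abort("upper band edge must be below the Nyquist frequency",
                 class = "oculaware_config_error")
  }
  hp <- signal::butter(2, band[1] / nyq, type = "high")
  lp <- signal::butter(4, band[2] / nyq, type = "low")
  y <- signal::filtfilt(hp, x)
  y <- signal::filtfilt(lp, y)
  for (f0 in notches) {
    edges <- c(f0 - notch_halfwidth_hz, f0 + notch_halfwidth_hz) / nyq
    if (edges[2] >= 1 || edges[1] <= 0) next
    bs <- signal::butter(2, edges, type = "stop")
    y <- signal::filtfilt(bs, y)
  }
  y
}

#' Segment a sensor trace into event-locked epochs
#'
#' Epochs are centered at `onset_ms + trigger_correction_ms` (the fixed
#' projector presentation delay, 19 ms in the reference setup) on a
#' symmetric grid of `2 * half_window_ms / step + 1` samples. Events whose
#' window extends outside the recording are dropped and reported in the
#' `dropped` attribute. Condition labels are taken from a `condition`
#' column when present, otherwise derived as `"<field>-stim"` for stimuli
#' and `"blank"` for blank events.
#'
#' @param trace Tibble with `t_ms` (uniform grid, any step) and `value`.
#' @param events Event tibble with `onset_ms` (and optionally `condition`,
#'   `field`, `is_blank`).
#' @param trigger_correction_ms Trigger-to-display delay added to onsets.
#' @param half_window_ms Epoch half-width, ms.
#' @return An `fp_epochs` object.
#' @export
epoch_field <- function(trace, events, trigger_correction_ms = 19,
                        half_window_ms = 4000) {
  stopifnot(all(c("t_ms", "value") %in% names(trace)), nrow(events) >= 1)
  step <- stats::median(diff(trace$t_ms))
  n_half <- round(half_window_ms / step)
  offsets_ms <- seq(-n_half, n_half) * step
  centres <- events$onset_ms + trigger_correction_ms
  centre_idx <- round((centres - trace$t_ms[1]) / step) + 1
  ok <- centre_idx - n_half >= 1 & centre_idx + n_half <= nrow(trace)
  if ("condition" %in% names(events)) {
    cond <- events$condition
  } else {
    is_blank <- if ("is_blank" %in% names(events)) events$is_blank else FALSE
    fld <- if ("field" %in% names(events)) events$field else "all"
    cond <- ifelse(is_blank, "blank", paste0(fld, "-stim"))
  }
  idx <- outer(centre_idx[ok], seq(-n_half, n_half), "+")
  data <- matrix(trace$value[idx], nrow = sum(ok))
  out <- structure(
    list(data = data, offsets_ms = offsets_ms,
         condition = factor(cond[ok]),
         sampling_rate = 1000 / step),
    class = "fp_epochs"
  )
  attr(out, "dropped") <- which(!ok)
  out
}

# Signed mass of the largest-magnitude supra-threshold cluster in a t-map
# (0 when no sample exceeds the threshold). Positive and negative
# exceedances form separate clusters.
max_cluster_mass <- function(t, thr) {
  lab <- integer(length(t))
  lab[t > thr] <- 1L
  lab[t < -thr] <- -1L
  if (all(lab == 0L)) return(0)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- 0
  for (i in which(r$values != 0L)) {
    m <- sum(t[starts[i]:ends[i]])
    if (abs(m) > abs(best)) best <- m
  }
  best
}

# All supra-threshold clusters of a t-map as a tibble of sample runs.
cluster_runs <- function(t, thr) {
  lab <- integer(length(t))
  lab[t > thr] <- 1L
  lab[t < -thr] <- -1L
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L)
  tibble::tibble(
    start_idx = starts[keep], end_idx = ends[keep],
    mass = vapply(keep, function(i) sum(t[starts[i]:ends[i]]), numeric(1))
  )
}

# Pooled-variance two-sample t per column, given group sums/sums of squares.
pooled_t <- function(s1, q1, s2, q2, n1, n2) {
  m1 <- s1 / n1; m2 <- s2 / n2
  ss1 <- pmax(0, q1 - s1^2 / n1)  # guard floating-point cancellation
  ss2 <- pmax(0, q2 - s2^2 / n2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  denom <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / denom
  t[!is.finite(t)] <- 0
  t
}

#' Cluster-based permutation test of two evoked-response conditions
#'
#' Epochs are baseline-corrected by their mean over the baseline interval;
#' per-sample pooled-variance two-sample t-statistics are computed over the
#' test window; contiguous runs of |t| above the two-sided critical value
#' at `cluster_alpha` form clusters whose mass is the sum of t within the
#' run. The null distribution of the maximum |cluster mass| is built by
#' `n_perm` random exchanges of the condition labels, and each observed
#' cluster receives p = (1 + #\{null >= |mass|\}) / (1 + n_perm).
#'
#' @param epochs An `fp_epochs` object, or a list `list(a = , b = )` of two
#'   epochs-by-samples matrices sharing `offsets_ms` (then `offsets_ms`
#'   must be given).
#' @param cond_a,cond_b Condition labels to contrast (for `fp_epochs`).
#' @param baseline,test_window Intervals in ms relative to the event.
#' @param n_perm Number of label permutations.
#' @param cluster_alpha Two-sided sample-level alpha forming clusters.
#' @param final_alpha Cluster-level significance threshold.
#' @param seed Seed for the permutation stream.
#' @param offsets_ms Offsets, only when matrices are supplied directly.
#' @return A `cluster_result`: tibble of clusters (`start_ms`, `end_ms`,
#'   `mass`, `p_value`, `significant`), the per-sample t trace, and the
#'   test configuration.
#' @export
cluster_permutation <- function(epochs, cond_a = NULL, cond_b = NULL,
                                baseline = c(-500, 0),
                                test_window = c(0, 500),
                                n_perm = 5000, cluster_alpha = 0.05,
                                final_alpha = 0.05, seed = 1,
                                offsets_ms = NULL) {
  if (inherits(epochs, "fp_epochs")) {
    stopifnot(!is.null(cond_a), !is.null(cond_b))
    a <- epochs$data[epochs$condition == cond_a, , drop = FALSE]
    b <- epochs$data[epochs$condition == cond_b, , drop = FALSE]
    offsets_ms <- epochs$offsets_ms
  } else {
    a <- epochs$a; b <- epochs$b
    stopifnot(!is.null(offsets_ms))
  }
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 < 2 || n2 < 2) {
    rlang::abort("need at least 2 epochs per condition",
                 class = "oculaware_data_error")
  }
  bl_cols <- which(offsets_ms >= baseline[1] & offsets_ms < baseline[2])
  te_cols <- which(offsets_ms > test_window[1] & offsets_ms <= test_window[2])
  stopifnot(length(bl_cols) > 0, length(te_cols) > 0)
  a <- a - rowMeans(a[, bl_cols, drop = FALSE])
  b <- b - rowMeans(b[, bl_cols, drop = FALSE])
  x <- rbind(a, b)[, te_cols, drop = FALSE]
  x2 <- x^2
  n <- n1 + n2
  s_tot <- colSums(x)
  q_tot <- colSums(x2)
  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 2)

  obs_t <- pooled_t(colSums(x[seq_len(n1), , drop = FALSE]),
                    colSums(x2[seq_len(n1), , drop = FALSE]),
                    s_tot - colSums(x[seq_len(n1), , drop = FALSE]),
                    q_tot - colSums(x2[seq_len(n1), , drop = FALSE]),
                    n1, n2)
  runs <- cluster_runs(obs_t, thr)

  # permutation null of the maximum |cluster mass|
  set.seed(as.integer(seed))
  perm <- matrix(0, nrow = n_perm, ncol = n)
  for (i in seq_len(n_perm)) perm[i, sample.int(n, n1)] <- 1
  s1 <- perm %*% x
  q1 <- perm %*% x2
  null_max <- vapply(seq_len(n_perm), function(i) {
    t_i <- pooled_t(s1[i, ], q1[i, ], s_tot - s1[i, ], q_tot - q1[i, ], n1, n2)
    abs(max_cluster_mass(t_i, thr))
  }, numeric(1))

  clusters <- tibble::tibble(
    start_ms = offsets_ms[te_cols][runs$start_idx],
    end_ms = offsets_ms[te_cols][runs$end_idx],
    mass = runs$mass,
    p_value = vapply(runs$mass, function(m) {
      (1 + sum(null_max >= abs(m))) / (1 + n_perm)
    }, numeric(1))
  )
  clusters$significant <- clusters$p_value <= final_alpha
  structure(
    list(clusters = clusters,
         t_trace = tibble::tibble(offset_ms = offsets_ms[te_cols], t = obs_t),
         n_perm = n_perm, cluster_alpha = cluster_alpha,
         final_alpha = final_alpha, threshold = thr,
         n_epochs = c(a = n1, b = n2)),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d vs %d epochs, %d permutation(s), |t| > %.2f\n",
              x$n_epochs[1], x$n_epochs[2], x$n_perm, x$threshold))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    min_p = if (nrow(x$clusters)) min(x$clusters$p_value) else NA_real_,
    n_perm = x$n_perm, threshold = x$threshold
  )
}
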