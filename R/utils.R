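# Shared numerical helpers. All timecourses in this package live on a uniform
# 1-ms grid unless a sampling step is given explicitly.

#' Centered moving average with shrinking edge windows
#'
#' Smooths a numeric vector with a centered moving average of width
#' `width` samples. Near the edges the window shrinks so the output keeps
#' the input length and never contains values extrapolated beyond the data.
#' `NA`s inside a window are dropped from that window's mean.
#'
#' @param x Numeric vector.
#' @param width Window width in samples; coerced to an odd integer >= 1.
#' @return Numeric vector, same length as `x`.
#' @export
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || length(x) == 0L) return(x)
  half <- (width - 1L) %/% 2L
  ok <- !is.na(x)
  xz <- ifelse(ok, x, 0)
  csum <- cumsum(c(0, xz))
  cnt <- cumsum(c(0, as.numeric(ok)))
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  s <- csum[hi + 1L] - csum[lo]
  k <- cnt[hi + 1L] - cnt[lo]
  out <- s / k
  out[k == 0] <- NA_real_
  out
}

#' Derive reproducible substream seeds from one master seed
#'
#' Expands a single master seed into named integer seeds, one per pipeline
#' component, so that components can be re-run or perturbed independently
#' without disturbing each other's random streams.
#'
#' @param seed Master seed (integer).
#' @param ids Character vector of substream names.
#' @return Named integer vector of seeds.
#' @export
substream_seeds <- function(seed, ids) {
  stopifnot(is.character(ids), length(ids) >= 1)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  draws <- sample.int(.Machine$integer.max - 1L, length(ids))
  stats::setNames(draws, ids)
}

# Convert a logical vector on the 1-ms grid into half-open intervals
# [start_ms, end_ms) using the time of the first sample `t0`.
runs_to_intervals <- function(flag, t0 = 0, step = 1) {
  r <- rle(as.logical(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble::tibble(
    start_ms = t0 + (starts[keep] - 1L) * step,
    end_ms = t0 + ends[keep] * step
  )
}

# Inverse of runs_to_intervals: mark samples of a grid of length n starting
# at t0 that fall inside any half-open interval [start_ms, end_ms).
intervals_to_flag <- function(intervals, n, t0 = 0, step = 1) {
  flag <- logical(n)
  if (is.null(intervals) || nrow(intervals) == 0) return(flag)
  for (i in seq_len(nrow(intervals))) {
    a <- ceiling((intervals$start_ms[i] - t0) / step) + 1
    b <- ceiling((intervals$end_ms[i] - t0) / step)
    a <- max(1, a); b <- min(n, b)
    if (a <= b) flag[a:b] <- TRUE
  }
  flag
}

# Pad logical runs by pad samples on each side, then merge runs separated by
# gaps shorter than merge_gap samples.
pad_and_merge <- function(flag, pad, merge_gap) {
  n <- length(flag)
  iv <- runs_to_intervals(flag)
  if (nrow(iv) == 0) return(flag)
  iv$start_ms <- pmax(0, iv$start_ms - pad)
  iv$end_ms <- pmin(n, iv$end_ms + pad)
  if (nrow(iv) > 1 && merge_gap > 0) {
    merged <- iv[1, ]
    for (i in 2:nrow(iv)) {
      gap <- iv$start_ms[i] - merged$end_ms[nrow(merged)]
      if (gap < merge_gap) {
        merged$end_ms[nrow(merged)] <- max(merged$end_ms[nrow(merged)], iv$end_ms[i])
      } else {
        merged <- rbind(merged, iv[i, ])
      }
    }
    iv <- merged
  }
  intervals_to_flag(iv, n)
}

#' Exact Wilcoxon signed-rank test with configurable zero handling
#'
#' One-sample signed-rank test of location against `mu`. For n of at most
#' `exact_limit` non-degenerate observations the null distribution is built
#' by exhaustive sign-flip enumeration, which remains exact under tied
#' absolute values (where the classical tables do not apply); larger samples
#' use a normal approximation with tie and continuity correction. Zero
#' differences are either discarded (`"wilcox"`) or kept in the ranking with
#' their signed contribution fixed at zero (`"pratt"`).
#'
#' @param x Numeric vector of observations (or paired differences).
#' @param mu Null location, default 0.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param zero_method `"pratt"` (default) or `"wilcox"`.
#' @param exact_limit Largest n for which sign flips are enumerated.
#' @return A tibble with `statistic` (sum of positive signed ranks), `n`
#'   (observations used), `p_value` and `method`.
#' @export
signed_rank_test <- function(x, mu = 0,
                             alternative = c("two.sided", "greater", "less"),
                             zero_method = c("pratt", "wilcox"),
                             exact_limit = 14L) {
  alternative <- match.arg(alternative)
  zero_method <- match.arg(zero_method)
  d <- x[!is.na(x)] - mu
  if (zero_method == "wilcox") d <- d[d != 0]
  n <- length(d)
  out <- function(stat, n_used, p) {
    tibble::tibble(
      statistic = stat, n = n_used, p_value = min(1, p),
      method = paste0("signed-rank (", zero_method, ")")
    )
  }
  if (n == 0 || all(d == 0)) {
    return(out(0, n, 1))
  }
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  nz <- which(d != 0)
  rs <- r[nz]
  if (length(nz) <= exact_limit) {
    # Enumerate all sign assignments of the non-zero ranks.
    w_null <- c(0)
    for (rk in rs) w_null <- c(w_null, w_null + rk)
    p_ge <- mean(w_null >= w_obs - 1e-12)
    p_le <- mean(w_null <= w_obs + 1e-12)
    p <- switch(alternative,
      greater = p_ge,
      less = p_le,
      two.sided = min(1, 2 * min(p_ge, p_le))
    )
    return(out(w_obs, n, p))
  }
  mu_w <- sum(rs) / 2
  sig_w <- sqrt(sum(rs^2) / 4)
  z_num <- w_obs - mu_w
  cc <- 0.5
  p <- switch(alternative,
    greater = stats::pnorm((z_num - cc) / sig_w, lower.tail = FALSE),
    less = stats::pnorm((z_num + cc) / sig_w),
    two.sided = 2 * stats::pnorm((abs(z_num) - cc) / sig_w, lower.tail = FALSE)
  )
  out(w_obs, n, p)
}

# Truncated-at-zero normal draws (rejection sampling; latency model).
rnorm_pos <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad) > 0 && guard < 1000L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
    guard <- guard + 1L
  }
  x[x <= 0] <- .Machine$double.eps
  x
}

stop_config <- function(field, msg) {
  rlang::abort(sprintf("invalid configuration `%s`: %s", field, msg),
               class = "oculaware_config_error")
}
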