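test_that("the synthetic evoked waveform has ordered N2 troughs", {
  amps <- list(
    sighted = c(P1 = 40, N2 = 120, LN = 60),
    blind = c(P1 = 15, N2 = 45, LN = 20)
  )
  fp <- generate_field_potential_epochs(60, amps, noise_sd = 30, seed = 4)
  m_s <- colMeans(fp$data[fp$condition == "sighted", ])
  m_b <- colMeans(fp$data[fp$condition == "blind", ])
  trough_cols <- fp$offsets_ms >= 100 & fp$offsets_ms <= 225
  expect_lt(min(m_s[trough_cols]), min(m_b[trough_cols]))
  expect_lt(min(m_b[trough_cols]), 0)
})

test_that("zero amplitudes give flat condition means", {
  amps <- list(null = c(P1 = 0, N2 = 0, LN = 0))
  fp <- generate_field_potential_epochs(80, amps, noise_sd = 20, seed = 5)
  m <- colMeans(fp$data)
  expect_lt(max(abs(m)), 4 * 20 / sqrt(80))
})

test_that("field-potential epochs are reproducible under a fixed seed", {
  amps <- list(a = c(P1 = 10, N2 = 20, LN = 5))
  x <- generate_field_potential_epochs(5, amps, seed = 6)
  y <- generate_field_potential_epochs(5, amps, seed = 6)
  expect_identical(x$data, y$data)
  expect_error(
    generate_field_potential_epochs(5, list(a = c(P1 = 1, N2 = 1))),
    "component_amps"
  )
})

test_that("the band-pass and notch filters shape the spectrum as intended", {
  fs <- 1200
  t <- seq(0, 10, by = 1 / fs)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  # 60-Hz line noise attenuated by at least 20 dB
  line <- sin(2 * pi * 60 * t)
  out <- preprocess_field(line, fs)
  expect_lt(max(abs(out[mid])), max(abs(line)) / 10)
  # in-band 10-Hz component preserved within 5%
  inband <- sin(2 * pi * 10 * t)
  out2 <- preprocess_field(inband, fs)
  expect_lt(abs(max(abs(out2[mid])) - 1), 0.05)
  # DC removed by the high-pass
  out3 <- preprocess_field(rep(5, length(t)), fs)
  expect_lt(max(abs(out3[mid])), 0.25)
  expect_error(preprocess_field(line, 200), "Nyquist")
})

test_that("the trigger correction aligns an impulse to offset zero", {
  trace <- tibble::tibble(t_ms = 0:2000, value = 0)
  trace$value[trace$t_ms == 519] <- 1
  ev <- tibble::tibble(onset_ms = 500)
  ep <- epoch_field(trace, ev, trigger_correction_ms = 19,
                    half_window_ms = 100)
  expect_equal(ep$data[1, ep$offsets_ms == 0], 1)
  expect_true(all(ep$data[1, ep$offsets_ms != 0] == 0))
  ep0 <- epoch_field(trace, ev, trigger_correction_ms = 0,
                     half_window_ms = 100)
  expect_equal(ep0$data[1, ep0$offsets_ms == 19], 1)
  # events whose window leaves the recording are dropped and logged
  ep_d <- epoch_field(trace, tibble::tibble(onset_ms = c(500, 1999)),
                      half_window_ms = 100)
  expect_equal(nrow(ep_d$data), 1)
  expect_equal(attr(ep_d, "dropped"), 2L)
})

test_that("identical condition epochs yield no supra-threshold samples", {
  base <- matrix(rep(sin(seq(-600, 600, by = 4) / 50), each = 6), nrow = 6,
                 byrow = FALSE)
  res <- cluster_permutation(list(a = base, b = base), n_perm = 100,
                             offsets_ms = seq(-600, 600, by = 4), seed = 2)
  expect_equal(nrow(res$clusters), 0)
})

test_that("an injected N2-like difference is found where it was injected", {
  amps <- list(
    stim = c(P1 = 30, N2 = 150, LN = 40),
    blank = c(P1 = 0, N2 = 0, LN = 0)
  )
  fp <- generate_field_potential_epochs(30, amps, noise_sd = 40, seed = 7)
  res <- cluster_permutation(fp, "stim", "blank", n_perm = 500, seed = 8)
  sig <- res$clusters[res$clusters$significant, ]
  expect_gt(nrow(sig), 0)
  expect_true(any(sig$start_ms < 225 & sig$end_ms > 100))
  # observed masses reproduce exactly under the same permutation seed
  res2 <- cluster_permutation(fp, "stim", "blank", n_perm = 500, seed = 8)
  expect_identical(res$clusters, res2$clusters)
})

test_that("swapping condition labels mirrors masses and keeps p-values", {
  amps <- list(
    stim = c(P1 = 20, N2 = 90, LN = 30),
    blank = c(P1 = 0, N2 = 0, LN = 0)
  )
  fp <- generate_field_potential_epochs(20, amps, noise_sd = 50, seed = 9)
  ab <- cluster_permutation(fp, "stim", "blank", n_perm = 500, seed = 10)
  ba <- cluster_permutation(fp, "blank", "stim", n_perm = 500, seed = 10)
  expect_equal(ab$clusters$mass, -ba$clusters$mass)
  expect_equal(ab$clusters$start_ms, ba$clusters$start_ms)
  # the sampled permutation nulls differ, so p-values agree statistically;
  # the dominant cluster must agree in location and significance
  expect_lt(max(abs(ab$clusters$p_value - ba$clusters$p_value)), 0.06)
  top_ab <- which.min(ab$clusters$p_value)
  top_ba <- which.min(ba$clusters$p_value)
  expect_equal(top_ab, top_ba)
  expect_identical(ab$clusters$significant[top_ab],
                   ba$clusters$significant[top_ba])
})
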