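test_that("config validation names the offending field", {
  expect_error(synth_config(stimulus_mix = c(white = 0.5, glare = 0.4)),
               "stimulus_mix")
  expect_error(synth_config(pre_stim_jitter = c(5, 3)), "pre_stim_jitter")
  expect_error(synth_config(blink_base_rate = -1), "blink_base_rate")
  expect_error(synth_config(perception_prob_by_field = c(sighted = 2, blind = 0)),
               "perception_prob_by_field")
})

test_that("a fixed seed reproduces the session exactly", {
  a <- generate_session(quick_config(seed = 5))
  b <- generate_session(quick_config(seed = 5))
  expect_identical(a$recording, b$recording)
  expect_identical(a$events, b$events)
  expect_identical(a$responses, b$responses)
  c <- generate_session(quick_config(seed = 6))
  expect_false(identical(a$recording$pupil, c$recording$pupil))
})

test_that("the recording grid and event log satisfy their invariants", {
  ses <- generate_session(quick_config(n_blocks = 2, seed = 3))
  expect_identical(diff(ses$recording$t_ms), rep(1L, nrow(ses$recording) - 1L))
  expect_identical(is.na(ses$recording$pupil), !ses$recording$valid)
  for (b in unique(ses$events$block)) {
    on <- ses$events$onset_ms[ses$events$block == b]
    expect_true(all(diff(on) > 0))
  }
  # consecutive onsets at least stim duration plus both jitter minima apart
  min_gap <- 3000 + 3000 + 3000
  expect_true(all(diff(ses$events$onset_ms) >= min_gap))
})

test_that("a no-signal configuration yields flat evoked averages", {
  cfg <- quick_config(
    trials_per_block = 40,
    dilation_amp = 0,
    constriction_amp_by_class = c(white = 0, glare = 0, nonglare = 0,
                                  isoluminant = 0),
    modulation_profiles = list(blink = c(onset = 1, offset = 1),
                               microsaccade = c(onset = 1, offset = 1)),
    blink_base_rate = 0,
    seed = 21
  )
  ses <- generate_session(cfg)
  ep <- extract_epochs(ses$recording, ses$events, epoch_window(),
                       signal = "pupil", baseline = TRUE)
  m <- epoch_mean(ep)
  post <- m$value[m$offset_ms > 0 & m$offset_ms <= 4000]
  expect_lt(max(abs(post)), 10)
})

test_that("perception probabilities 1 and 0 give rates 1 and 0 per field", {
  cfg <- quick_config(trials_per_block = 40,
                      perception_prob_by_field = c(sighted = 1, blind = 0),
                      seed = 8)
  ses <- generate_session(cfg)
  rates <- score_perception(ses$events, ses$responses)
  expect_equal(rates$perception_rate[rates$field == "sighted"], 1)
  expect_equal(rates$perception_rate[rates$field == "blind"], 0)
})

test_that("blink and microsaccade counts match rate expectations over seeded runs", {
  # dead-time-corrected expectation for a thinned point process:
  # lambda_eff = lambda / (1 + lambda * tau)
  n_runs <- 20
  counts <- vapply(seq_len(n_runs), function(s) {
    cfg <- quick_config(
      modulation_profiles = list(blink = c(onset = 1, offset = 1),
                                 microsaccade = c(onset = 1, offset = 1)),
      seed = 100 + s
    )
    ses <- generate_session(cfg)
    c(blinks = nrow(ses$truth$blinks),
      ms = nrow(ses$truth$microsaccades),
      dur_s = nrow(ses$recording) / 1000)
  }, numeric(3))
  total_s <- sum(counts["dur_s", ])
  lam_b <- 0.25 / (1 + 0.25 * 0.21)   # blink dead time ~ duration + ramp
  lam_m <- 1.5 / (1 + 1.5 * 0.051)    # refractory gap 50 ms
  for (spec in list(c("blinks", lam_b), c("ms", lam_m))) {
    obs <- sum(counts[spec[1], ])
    expec <- as.numeric(spec[2]) * total_s
    expect_lt(abs(obs - expec), 3 * sqrt(expec))
  }
})

test_that("injected kernel amplitude is recovered from clean epochs", {
  amp <- -120
  cfg <- synth_config(
    n_blocks = 1, trials_per_block = 200,
    stimulus_mix = c("target-plus" = 0, "target-x" = 0, white = 1,
                     glare = 0, nonglare = 0, isoluminant = 0),
    field_mix = c(sighted = 1, blind = 0),
    constriction_amp_by_class = c(white = amp, glare = 0, nonglare = 0,
                                  isoluminant = 0),
    blink_base_rate = 0,
    perception_prob_by_field = c(sighted = 0, blind = 0),
    seed = 31
  )
  ses <- generate_session(cfg)
  ep <- extract_epochs(ses$recording, ses$events, epoch_window(),
                       signal = "pupil", baseline = TRUE)
  m <- epoch_mean(ep)
  plateau <- mean(m$value[m$offset_ms >= 1200 & m$offset_ms <= 2800])
  expect_lt(abs(plateau - amp), abs(amp) * 0.05)
})
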