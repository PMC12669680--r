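toy_events <- function(onsets, class = "white", field = "sighted",
                       block = 1L) {
  tibble::tibble(onset_ms = onsets, event_class = class, field = field,
                 block = block, event_id = seq_along(onsets),
                 is_blank = FALSE)
}

test_that("blank events respect the interstimulus constraints", {
  events <- toy_events(c(1000, 11000))
  draws <- purrr::map_dfr(1:300, function(s) {
    sample_blank_events(events, block_end_ms = 21000, seed = s)
  })
  first <- draws[draws$pair_id == 1, ]
  expect_true(all(first$onset_ms >= 5000 & first$onset_ms <= 10000))
  last <- draws[draws$pair_id == 2, ]
  expect_true(all(last$onset_ms >= 15000 & last$onset_ms <= 18000))
})

test_that("the final blank of a block precedes the block end", {
  events <- toy_events(c(1000))
  bl <- sample_blank_events(events, block_end_ms = 6500, seed = 2)
  expect_true(all(bl$onset_ms <= 6500 & bl$onset_ms >= 5000))
  # empty admissible interval: blank omitted and reported
  none <- sample_blank_events(events, block_end_ms = 4500, seed = 2)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "omitted"), 1L)
})

test_that("blank sampling is reproducible under a fixed seed", {
  events <- toy_events(c(1000, 12000, 24000))
  a <- sample_blank_events(events, 34000, seed = 10)
  b <- sample_blank_events(events, 34000, seed = 10)
  expect_identical(a$onset_ms, b$onset_ms)
})

test_that("baselining a constant trace gives exactly zero epochs", {
  rec <- flat_recording(30000, pupil = 950)
  ep <- extract_epochs(rec, toy_events(15000), epoch_window(half_ms = 2000),
                       baseline = TRUE)
  expect_true(all(ep$data == 0))
})

test_that("a step at the event onset survives baselining intact", {
  rec <- flat_recording(30000, pupil = 100)
  rec$pupil[rec$t_ms >= 15000] <- 110
  ep <- extract_epochs(rec, toy_events(15000), epoch_window(half_ms = 2000),
                       baseline = TRUE)
  off <- seq(-2000, 2000)
  expect_equal(unname(ep$data[1, off < 0]), rep(0, sum(off < 0)))
  expect_equal(unname(ep$data[1, off >= 0]), rep(10, sum(off >= 0)))
})

test_that("binary epochs pass through unchanged and refuse baselining", {
  tc <- structure(list(values = rep(1L, 30000), kind = "blink",
                       intervals = tibble::tibble(start_ms = 0, end_ms = 30000),
                       t0 = 0), class = "event_timecourse")
  ep <- extract_epochs(tc, toy_events(15000), epoch_window(half_ms = 2000))
  expect_true(all(ep$data == 1))
  expect_error(extract_epochs(tc, toy_events(15000),
                              epoch_window(half_ms = 2000), baseline = TRUE),
               "never baselined")
})

test_that("baselined epochs have zero baseline mean on real sessions", {
  ses <- generate_session(quick_config(seed = 61))
  bl <- detect_blinks(ses$recording)
  clean <- clean_pupil(ses$recording, bl)
  ep <- extract_epochs(clean, ses$events, epoch_window(), baseline = TRUE)
  bl_cols <- ep$offsets_ms >= -1000 & ep$offsets_ms <= -1
  bmeans <- rowMeans(ep$data[, bl_cols], na.rm = TRUE)
  expect_true(all(abs(bmeans) < 1e-9, na.rm = TRUE))
})

test_that("epoch extraction commutes with a joint time shift", {
  rec <- flat_recording(20000)
  set.seed(9)
  rec$pupil <- 1000 + cumsum(rnorm(20000, 0, 0.1))
  ev <- toy_events(c(6000, 12000))
  ep1 <- extract_epochs(rec, ev, epoch_window(half_ms = 1500))
  shifted <- rec
  shifted$t_ms <- shifted$t_ms + 5000L
  ev2 <- dplyr::mutate(ev, onset_ms = onset_ms + 5000)
  ep2 <- extract_epochs(shifted, ev2, epoch_window(half_ms = 1500))
  expect_identical(ep1$data, ep2$data)
})

test_that("exclusion boundaries follow the strict rules", {
  win <- epoch_window(half_ms = 7000)
  n_analysis <- 7001  # -1000..6000 inclusive
  rec <- flat_recording(40000, pupil = 1000)
  ev <- toy_events(c(10000, 25000))
  # one extreme sample (1751) inside the first epoch's analysis interval
  rec$pupil[rec$t_ms == 10500] <- 1751
  ep <- extract_epochs(rec, ev, win)
  ep <- apply_pupil_exclusion(ep)
  expect_identical(ep$included, c(FALSE, TRUE))
  expect_identical(ep$exclusion_reason[1], "extreme")

  # exactly 50% missing is retained; strictly more than 50% is excluded
  rec2 <- flat_recording(40000, pupil = 1000)
  half <- floor(n_analysis / 2)
  rec2$pupil[rec2$t_ms >= 9000 & rec2$t_ms < 9000 + half] <- NA
  rec2$pupil[rec2$t_ms >= 24000 & rec2$t_ms < 24000 + half + 200] <- NA
  ep2 <- apply_pupil_exclusion(extract_epochs(rec2, ev, win))
  expect_identical(ep2$included, c(TRUE, FALSE))
  expect_identical(ep2$exclusion_reason[2], "missing")

  # value at exactly the threshold is retained (strict >)
  rec3 <- flat_recording(40000, pupil = 1000)
  rec3$pupil[rec3$t_ms == 10500] <- 1750
  ep3 <- apply_pupil_exclusion(extract_epochs(rec3, ev, win))
  expect_true(all(ep3$included))
})

test_that("binary exclusion uses tracking validity, or zeros when literal", {
  win <- epoch_window(half_ms = 7000)
  ev <- toy_events(c(10000, 25000))
  tc <- structure(list(values = integer(40000), kind = "blink",
                       intervals = tibble::tibble(start_ms = numeric(0),
                                                  end_ms = numeric(0)),
                       t0 = 0), class = "event_timecourse")
  validity <- flat_recording(40000)
  validity$tracked <- 1
  # second epoch: 60% of the analysis interval untracked
  validity$tracked[validity$t_ms >= 24000 & validity$t_ms < 24000 + 4300] <- 0
  val_ep <- extract_epochs(validity, ev, win, signal = "tracked")
  ep <- apply_binary_exclusion(extract_epochs(tc, ev, win), validity = val_ep)
  expect_identical(ep$included, c(TRUE, FALSE))
  # literal variant would exclude both all-zero epochs
  lit <- apply_binary_exclusion(extract_epochs(tc, ev, win), literal = TRUE)
  expect_identical(lit$included, c(FALSE, FALSE))
})

test_that("a clean synthetic session loses under 15% of epochs and keeps pairing", {
  ses <- generate_session(quick_config(trials_per_block = 30, seed = 55))
  blanks <- sample_blank_events(ses$events, ses$block_end_ms, seed = 56)
  all_ev <- dplyr::bind_rows(
    dplyr::mutate(ses$events, pair_id = event_id), blanks
  )
  bl <- detect_blinks(ses$recording)
  clean <- clean_pupil(ses$recording, bl)
  raw <- extract_epochs(ses$recording, all_ev, epoch_window())
  ep <- extract_epochs(clean, all_ev, epoch_window(), baseline = TRUE)
  ep <- apply_pupil_exclusion(ep, raw = raw)
  expect_lt(glance(ep)$exclusion_fraction, 0.15)
  ep <- harmonise_pairs(ep)
  inc <- tidy(ep)[ep$included, ]
  stim <- inc[!inc$is_blank, ]
  blank <- inc[inc$is_blank, ]
  # bijection between included stimulus epochs and included blank epochs
  expect_setequal(stim$event_id, blank$pair_id)
  expect_equal(anyDuplicated(blank$pair_id), 0)
})

test_that("fraction traces average binary epochs and smooth the mean", {
  win <- epoch_window(half_ms = 2000)
  ev <- toy_events(c(10000, 20000))
  ones <- structure(list(values = rep(1L, 30000), kind = "microsaccade",
                         intervals = tibble::tibble(start_ms = 0, end_ms = 30000),
                         t0 = 0), class = "event_timecourse")
  ep <- extract_epochs(ones, ev, win)
  tr <- fraction_timecourse(ep, smooth_ms = 1)
  expect_true(all(tr$mean == 1))
  expect_true(all(tr$sem == 0))
  # one all-zero and one all-one epoch average to one half
  ep$data[1, ] <- 0
  tr2 <- fraction_timecourse(ep, smooth_ms = 1)
  expect_true(all(tr2$mean == 0.5))
  ep$included <- c(FALSE, FALSE)
  expect_error(fraction_timecourse(ep), "no epochs")
})

test_that("an injected suppression profile is recovered from fraction traces", {
  cfg <- synth_config(
    n_blocks = 2, trials_per_block = 200,
    microsaccade_base_rate = 1.5,
    modulation_profiles = list(blink = c(onset = 1, offset = 1),
                               microsaccade = c(onset = 0.2, offset = 1)),
    blink_base_rate = 0,
    perception_prob_by_field = c(sighted = 0, blind = 0),
    seed = 71
  )
  ses <- generate_session(cfg)
  tr <- ses$truth$microsaccades
  flag <- oculaware:::intervals_to_flag(
    tibble::tibble(start_ms = tr$onset_ms, end_ms = tr$onset_ms + tr$duration_ms),
    nrow(ses$recording)
  )
  tc <- structure(list(values = as.integer(flag), kind = "microsaccade",
                       intervals = tibble::tibble(start_ms = tr$onset_ms,
                                                  end_ms = tr$onset_ms + tr$duration_ms),
                       t0 = 0), class = "event_timecourse")
  ep <- extract_epochs(tc, ses$events, epoch_window())
  fr <- fraction_timecourse(ep, smooth_ms = 1)
  pre <- mean(fr$mean[fr$offset_ms >= -1000 & fr$offset_ms <= -1])
  supp <- mean(fr$mean[fr$offset_ms >= 1 & fr$offset_ms <= 500])
  ratio <- supp / pre
  expect_lt(abs(ratio - 0.2), 0.2 * 0.2)
  # and the suppression window sits below the pre-stimulus rate
  expect_lt(supp, pre)
})
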