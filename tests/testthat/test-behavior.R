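make_targets <- function(onsets, class = "target-plus", field = "blind") {
  tibble::tibble(onset_ms = onsets, event_class = class, field = field,
                 block = 1L, event_id = seq_along(onsets), is_blank = FALSE)
}

test_that("perception rate is perceived over presented, per field", {
  onsets <- seq(1000, by = 10000, length.out = 100)
  ev <- make_targets(onsets)
  # 54 of 100 presented targets answered
  resp <- tibble::tibble(press_ms = onsets[1:54] + 800, key = "plus")
  out <- score_perception(ev, resp)
  expect_equal(out$perception_rate, 0.54)
  expect_equal(out$n_perceived, 54)
  expect_equal(out$false_positive_rate, 0)
})

test_that("no responses give rate 0 and undefined false positives", {
  ev <- make_targets(c(1000, 11000))
  out <- score_perception(ev, tibble::tibble(press_ms = numeric(0),
                                             key = character(0)))
  expect_equal(out$perception_rate, 0)
  expect_true(is.na(out$false_positive_rate))
})

test_that("each press answers at most one target and extras count as false alarms", {
  ev <- make_targets(c(1000, 2000))
  # one press inside both windows, one press far outside any window
  resp <- tibble::tibble(press_ms = c(2500, 50000), key = c("plus", "plus"))
  out <- score_perception(ev, resp)
  expect_equal(out$n_perceived, 1)
  expect_equal(out$false_positive_rate, 0.5)
  m <- attr(out, "matches")
  expect_equal(sum(!is.na(m$press_ms)), 1)
  # matched fraction of presses plus false-positive rate is one
  expect_equal(sum(!is.na(m$press_ms)) / nrow(resp) + out$false_positive_rate, 1)
})

test_that("all targets answered promptly give rate 1 and zero false alarms", {
  onsets <- seq(1000, by = 9000, length.out = 20)
  ev <- make_targets(onsets)
  resp <- tibble::tibble(press_ms = onsets + 100, key = "plus")
  out <- score_perception(ev, resp)
  expect_equal(out$perception_rate, 1)
  expect_equal(out$false_positive_rate, 0)
  expect_true(all(unlist(out$rts) == 0.1))
})

test_that("orientation accuracy reproduces the 34-of-54 case", {
  onsets <- seq(1000, by = 10000, length.out = 54)
  cls <- rep(c("target-plus", "target-x"), 27)
  ev <- make_targets(onsets, class = cls)
  correct_key <- ifelse(cls == "target-plus", "plus", "x")
  wrong_key <- ifelse(cls == "target-plus", "x", "plus")
  key <- c(correct_key[1:34], wrong_key[35:54])
  perc <- score_perception(ev, tibble::tibble(press_ms = onsets + 500,
                                              key = key))
  acc <- score_orientation(perc)
  expect_equal(acc$n_correct, 34)
  expect_equal(acc$accuracy, 34 / 54)
  expect_equal(round(acc$accuracy, 2), 0.63)
})

test_that("orientation accuracy is undefined for the one-target task", {
  ev <- make_targets(c(1000, 11000), class = "target-plus")
  perc <- score_perception(ev, tibble::tibble(press_ms = c(1500, 11500),
                                              key = c("plus", "plus")))
  acc <- score_orientation(perc)
  expect_true(all(is.na(acc$accuracy)))
  expect_match(attr(acc, "undefined_reason"), "one-target")
})

test_that("random keys land near chance orientation accuracy", {
  set.seed(33)
  n <- 200
  onsets <- seq(1000, by = 9000, length.out = n)
  cls <- sample(c("target-plus", "target-x"), n, replace = TRUE)
  ev <- make_targets(onsets, class = cls)
  key <- sample(c("plus", "x"), n, replace = TRUE)
  acc <- score_orientation(
    score_perception(ev, tibble::tibble(press_ms = onsets + 400, key = key))
  )
  ci <- qbinom(c(0.025, 0.975), n, 0.5) / n
  expect_gte(acc$accuracy, ci[1])
  expect_lte(acc$accuracy, ci[2])
})

test_that("the exact binomial tail matches closed forms and enumeration", {
  expect_equal(binomial_above_chance(10, 10, 0.5), 0.5^10)
  expect_equal(binomial_above_chance(0, 7, 0.5), 1)
  # exhaustive outcome enumeration for small n
  for (case in list(c(6, 10, 0.5), c(4, 9, 0.3), c(12, 12, 0.6))) {
    k <- case[1]; n <- case[2]; p <- case[3]
    outcomes <- expand.grid(rep(list(c(0, 1)), n))
    succ <- rowSums(outcomes)
    prob <- p^succ * (1 - p)^(n - succ)
    expect_equal(binomial_above_chance(k, n, p), sum(prob[succ >= k]),
                 tolerance = 1e-12)
  }
  expect_error(binomial_above_chance(5, 4), "k")
})

test_that("identical reaction-time samples give the maximal p-value", {
  x <- rep(1.2, 10)
  out <- compare_rt(x, x)
  expect_equal(out$p_value, 1)
})

test_that("a constant shift is detected by the paired test", {
  set.seed(12)
  a <- rnorm(20, 1, 0.2)
  out <- compare_rt(a, a + 1)
  expect_lt(out$p_value, 0.01)
  # unequal lengths are trimmed and flagged
  out2 <- compare_rt(a, c(a, 2) + 1)
  expect_match(out2$note, "trimmed")
  expect_equal(out2$n_a, 20)
  skip <- compare_rt(a, 1)
  expect_match(skip$note, "skipped")
})

test_that("the paired test holds its type-I error rate on null data", {
  set.seed(99)
  n_rep <- 1000
  p <- vapply(seq_len(n_rep), function(i) {
    a <- rnorm(10)
    b <- rnorm(10)
    compare_rt(a, b)$p_value
  }, numeric(1))
  rate <- mean(p <= 0.05)
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("the correspondence designations follow the strict thresholds", {
  data <- tibble::tibble(
    participant = c("P8", "Pb", "Pz"),
    perception_rate = c(0.06, 0.26, 0),
    verbal_fraction = c(0.5, 0.05, 0),
    eye_present = c(TRUE, FALSE, FALSE)
  )
  out <- correspondence_table(data)
  expect_equal(out$task_behavior, c("absent", "present", "absent"))
  expect_equal(out$verbal_report, c("present", "absent", "absent"))
  expect_equal(out$eye_metrics, c("present", "absent", "absent"))
  expect_equal(unname(attr(out, "n_agree")), 1)
  expect_true(out$agree[3])
})
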