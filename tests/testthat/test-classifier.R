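# Direct construction of aligned epoch features: n_pairs stimulus/blank
# pairs, optionally separable by a mean shift on the stimulus epochs.
toy_features <- function(n_pairs, n_feat = 20, effect = 0, seed = 1) {
  set.seed(seed)
  n <- 2 * n_pairs
  labels <- rep(c("stimulus", "blank"), n_pairs)
  pair <- rep(seq_len(n_pairs), each = 2)
  x <- matrix(rnorm(n * n_feat), n)
  x[labels == "stimulus", ] <- x[labels == "stimulus", ] + effect
  rownames(x) <- seq_len(n)
  list(x = x, labels = labels,
       meta = tibble::tibble(event_id = seq_len(n), pair_id = pair))
}

test_that("feature binning averages consecutive windows", {
  rec <- flat_recording(30000)
  rec$pupil <- as.numeric(rec$t_ms)  # value equals time
  ev <- tibble::tibble(onset_ms = 10000, event_class = "white",
                       field = "sighted", block = 1L, event_id = 1L,
                       is_blank = FALSE)
  ep <- extract_epochs(rec, ev, epoch_window(half_ms = 9000))
  # bin width equal to the window gives a single feature: the window mean
  f1 <- build_feature_matrix(ep, feature_end_ms = 4000, bin_ms = 4000)
  expect_equal(dim(f1), c(1, 1))
  expect_equal(unname(f1[1, 1]), mean(10000 + 1:4000))
  # default binning gives 200 features
  f200 <- build_feature_matrix(ep)
  expect_equal(ncol(f200), 200)
  expect_equal(unname(f200[1, 1]), mean(10000 + 1:20))
  # constant epochs give constant features
  rec$pupil <- 7
  epc <- extract_epochs(rec, ev, epoch_window(half_ms = 9000))
  fc <- build_feature_matrix(epc)
  expect_true(all(fc == 7))
  expect_error(build_feature_matrix(ep, bin_ms = 33), "divide")
})

test_that("folds partition pairs and keep pair members together", {
  tf <- toy_features(30)
  folds <- make_folds(tf$meta, k = 10, seed = 2)
  expect_setequal(unique(folds$fold), 1:10)
  by_pair <- tapply(folds$fold, folds$pair_id, function(f) length(unique(f)))
  expect_true(all(by_pair == 1))
  # data-independent: same meta, same seed, same assignment
  expect_identical(folds, make_folds(tf$meta, k = 10, seed = 2))
})

test_that("separable data is classified nearly perfectly", {
  tf <- toy_features(30, effect = 3, seed = 3)
  folds <- make_folds(tf$meta, k = 10, seed = 3)
  fit <- fit_stacked_classifier(
    list(pupil = tf$x, blink = tf$x, microsaccade = tf$x),
    tf$labels, folds
  )
  expect_gte(fit$accuracy, 0.9)
  expect_equal(fit$chance, 0.5)
  expect_equal(fit$n_epochs, 60)
  expect_true(all(!is.na(fit$scores$score_stack)))
})

test_that("accuracy is invariant to epoch order shuffling given fixed folds", {
  tf <- toy_features(20, effect = 1.5, seed = 4)
  folds <- make_folds(tf$meta, k = 5, seed = 4)$fold
  fit1 <- fit_stacked_classifier(list(m = tf$x), tf$labels, folds)
  set.seed(5)
  ord <- sample(length(tf$labels))
  fit2 <- fit_stacked_classifier(list(m = tf$x[ord, ]), tf$labels[ord],
                                 folds[ord])
  expect_equal(fit1$accuracy, fit2$accuracy)
})

test_that("a stack with one informative metric beats the noise-only metrics", {
  tf_sig <- toy_features(30, effect = 2, seed = 6)
  tf_n1 <- toy_features(30, effect = 0, seed = 7)
  tf_n2 <- toy_features(30, effect = 0, seed = 8)
  folds <- make_folds(tf_sig$meta, k = 10, seed = 6)
  fit <- fit_stacked_classifier(
    list(pupil = tf_sig$x, blink = tf_n1$x, microsaccade = tf_n2$x),
    tf_sig$labels, folds
  )
  noise_best <- max(fit$metric_accuracy[c("blink", "microsaccade")])
  expect_gte(fit$accuracy, noise_best)
  expect_gt(fit$accuracy, 0.7)
})

test_that("a class missing from a training split names the fold", {
  x <- matrix(rnorm(12), 6)
  labels <- c("stimulus", "stimulus", "stimulus", "blank", "blank", "blank")
  folds <- c(1, 1, 1, 2, 2, 2)
  expect_error(fit_stacked_classifier(list(m = x), labels, folds), "fold")
  expect_error(
    fit_stacked_classifier(list(m = x[1:3, ]), labels[1:3], folds[1:3]),
    "2 epochs per class"
  )
})

test_that("permuted labels drive the stack to chance (no leakage)", {
  tf <- toy_features(24, effect = 2.5, seed = 9)
  folds <- make_folds(tf$meta, k = 8, seed = 9)
  null <- permutation_null(
    list(pupil = tf$x, blink = tf$x, microsaccade = tf$x),
    tf$labels, folds, n_perm = 60, seed = 10
  )
  n <- length(tf$labels)
  half_width <- 1.96 * sqrt(0.25 / n)
  expect_lt(abs(mean(null$accuracy) - 0.5), half_width)
  # while the true labels are decodable on the same folds
  fit <- fit_stacked_classifier(
    list(pupil = tf$x, blink = tf$x, microsaccade = tf$x), tf$labels, folds
  )
  expect_gt(fit$accuracy, stats::quantile(null$accuracy, 0.95))
})

test_that("the presence criterion flags only decodable metrics", {
  tf_sig <- toy_features(24, effect = 2.5, seed = 11)
  tf_noise <- toy_features(24, effect = 0, seed = 12)
  folds <- make_folds(tf_sig$meta, k = 8, seed = 11)
  feats <- list(pupil = tf_sig$x, blink = tf_noise$x,
                microsaccade = tf_noise$x)
  fit <- fit_stacked_classifier(feats, tf_sig$labels, folds)
  null <- permutation_null(feats, tf_sig$labels, folds, n_perm = 40, seed = 13)
  pres <- eye_metric_presence(fit, null)
  expect_true(pres$present[pres$metric == "pupil"])
})
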