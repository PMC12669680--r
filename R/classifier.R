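# Two-level stacked linear-SVM classification of stimulus vs blank epochs.

#' Bin epoch samples into a feature matrix
#'
#' Features for the epoch-level classifiers are the epoch samples in
#' `(0, feature_end_ms]` after event onset, averaged in consecutive
#' non-overlapping bins of `bin_ms` (defaults: 4000 ms in 20-ms bins,
#' giving 200 features). `bin_ms = 1` keeps the raw samples. Only included
#' epochs contribute rows.
#'
#' @param epochs An `epoch_set` (baselined pupil or raw binary).
#' @param feature_end_ms End of the post-onset feature window, ms.
#' @param bin_ms Bin width, ms; must divide `feature_end_ms`.
#' @return Numeric matrix (epochs x features) with `event_id` rownames and
#'   a `meta` attribute holding the included epochs' metadata.
#' @export
build_feature_matrix <- function(epochs, feature_end_ms = 4000, bin_ms = 20) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (feature_end_ms %% bin_ms != 0) {
    rlang::abort("`bin_ms` must divide `feature_end_ms`")
  }
  cols <- which(epochs$offsets_ms >= 1 & epochs$offsets_ms <= feature_end_ms)
  stopifnot(length(cols) == feature_end_ms)
  d <- epochs$data[epochs$included, cols, drop = FALSE]
  n_bins <- feature_end_ms / bin_ms
  if (bin_ms == 1) {
    feat <- d
  } else {
    grp <- rep(seq_len(n_bins), each = bin_ms)
    feat <- t(apply(d, 1, function(r) tapply(r, grp, mean, na.rm = TRUE)))
    if (nrow(d) == 1) feat <- matrix(feat, nrow = 1)
    dimnames(feat) <- NULL
  }
  feat[is.nan(feat)] <- 0
  feat[is.na(feat)] <- 0
  rownames(feat) <- epochs$meta$event_id[epochs$included]
  attr(feat, "meta") <- tidy(epochs)[epochs$included, ]
  feat
}

#' Assign cross-validation folds to stimulus/blank epoch pairs
#'
#' Folds are assigned to epoch *pairs*, so a stimulus epoch and its
#' temporally adjacent blank always share a fold and can never leak across
#' the train/test split. Because every pair holds one epoch of each class,
#' fold assignment is automatically stratified by label. Assignment
#' depends only on the pair identifiers and the seed, never on the data.
#'
#' @param meta Epoch metadata tibble with `event_id` and `pair_id`
#'   (e.g. `tidy(epoch_set)` restricted to included epochs).
#' @param k Number of folds.
#' @param seed Seed for the shuffle.
#' @return Tibble with `event_id`, `pair_id`, `fold`.
#' @export
make_folds <- function(meta, k = 10, seed = 1) {
  stopifnot(all(c("event_id", "pair_id") %in% names(meta)))
  pairs <- unique(meta$pair_id)
  if (length(pairs) < k) {
    rlang::abort(sprintf("%d pairs cannot fill %d folds", length(pairs), k))
  }
  set.seed(as.integer(seed))
  shuffled <- sample(pairs)
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(pairs)),
                             shuffled)
  tibble::tibble(
    event_id = meta$event_id,
    pair_id = meta$pair_id,
    fold = as.integer(fold_of[as.character(meta$pair_id)])
  )
}

# Standardize train columns; apply the same transform to test.
standardize_pair <- function(train, test) {
  mu <- colMeans(train)
  s <- apply(train, 2, stats::sd)
  s[s == 0 | is.na(s)] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, s, "/"),
       test = sweep(sweep(test, 2, mu), 2, s, "/"))
}

# Out-of-fold signed decision scores of a linear SVM, oriented so that
# positive scores favour the "stimulus" class.
oof_svm_scores <- function(x, labels, fold, cost) {
  n <- nrow(x)
  scores <- rep(NA_real_, n)
  for (f in sort(unique(fold))) {
    tr <- fold != f
    te <- !tr
    if (length(unique(labels[tr])) < 2) {
      rlang::abort(sprintf("a class is absent from the training split of fold %d", f),
                   class = "oculaware_data_error")
    }
    std <- standardize_pair(x[tr, , drop = FALSE], x[te, , drop = FALSE])
    fit <- e1071::svm(std$train, factor(labels[tr], levels = c("blank", "stimulus")),
                      kernel = "linear", cost = cost, scale = FALSE)
    pr <- predict(fit, std$test, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient: the decision-value column is named "A/B" with positive
    # favouring A
    pos_class <- strsplit(colnames(dv)[1], "/")[[1]][1]
    s <- as.numeric(dv[, 1])
    if (pos_class != "stimulus") s <- -s
    scores[te] <- s
  }
  scores
}

#' Fit the two-level stacked epoch classifier
#'
#' First level: for each eye metric, a linear support vector machine is
#' trained per fold on the remaining folds (features standardized on the
#' training fold) and produces signed distances from the decision boundary
#' for its held-out fold. Second level: a linear SVM takes the three
#' out-of-fold first-level scores as features and is trained and evaluated
#' with the *same* fold partition (nested cross-validation), so no epoch's
#' second-level input was produced by a model that saw that epoch. The
#' final per-epoch predictions are the second-level held-out predictions;
#' a second-level score of exactly 0 predicts `"blank"`.
#'
#' @param features Named list of feature matrices (one per metric, same
#'   rows in the same order), from [build_feature_matrix()].
#' @param labels Character/factor vector per epoch: `"stimulus"` or
#'   `"blank"`.
#' @param folds Integer fold id per epoch, or the tibble from
#'   [make_folds()] (matched by row order).
#' @param cost SVM regularization parameter.
#' @return A `stacked_fit`: per-epoch tibble of first-level scores, stack
#'   score, prediction and label; overall `accuracy`; `chance` (majority
#'   class proportion); per-metric accuracies from the first-level scores.
#' @export
fit_stacked_classifier <- function(features, labels, folds, cost = 1) {
  if (is.matrix(features)) features <- list(metric = features)
  stopifnot(is.list(features), length(features) >= 1)
  n <- length(labels)
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("stimulus", "blank")))
  if (is.data.frame(folds)) folds <- folds$fold
  stopifnot(length(folds) == n)
  for (m in names(features)) {
    stopifnot(nrow(features[[m]]) == n)
  }
  tab <- table(factor(labels, levels = c("blank", "stimulus")))
  if (min(tab) < 2) {
    rlang::abort("need at least 2 epochs per class", class = "oculaware_data_error")
  }
  first <- lapply(features, function(f) {
    oof_svm_scores(f, labels, folds, cost)
  })
  x2 <- do.call(cbind, first)
  colnames(x2) <- names(features)
  stack_score <- oof_svm_scores(x2, labels, folds, cost)
  predicted <- ifelse(stack_score > 0, "stimulus", "blank")
  accuracy <- mean(predicted == labels)
  chance <- max(table(labels)) / n
  metric_accuracy <- vapply(first, function(s) {
    mean(ifelse(s > 0, "stimulus", "blank") == labels)
  }, numeric(1))
  scores <- tibble::tibble(fold = as.integer(folds), label = labels)
  for (m in names(features)) scores[[paste0("score_", m)]] <- first[[m]]
  scores$score_stack <- stack_score
  scores$predicted <- predicted
  structure(
    list(scores = scores, accuracy = accuracy, chance = chance,
         metric_accuracy = metric_accuracy, n_epochs = n, cost = cost),
    class = "stacked_fit"
  )
}

#' @export
print.stacked_fit <- function(x, ...) {
  cat(sprintf("<stacked_fit> %d epochs, accuracy %.3f (chance %.3f)\n",
              x$n_epochs, x$accuracy, x$chance))
  cat("  first-level:",
      paste(sprintf("%s %.3f", names(x$metric_accuracy), x$metric_accuracy),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.stacked_fit <- function(x, ...) x$scores

#' @export
glance.stacked_fit <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, chance = x$chance,
                 n_epochs = x$n_epochs, cost = x$cost)
}

#' Permuted-label null distribution of stacked accuracy
#'
#' Refits the full stacked classifier on randomly permuted labels (fold
#' assignment held fixed) to obtain the null distribution of accuracy.
#' Used both as a leakage check (the null must centre on chance) and to
#' calibrate the eye-metric presence criterion.
#'
#' @inheritParams fit_stacked_classifier
#' @param n_perm Number of label permutations.
#' @param seed Seed for the permutation stream.
#' @return Tibble with `perm`, `accuracy`, and per-metric accuracies.
#' @export
permutation_null <- function(features, labels, folds, cost = 1,
                             n_perm = 200, seed = 1) {
  set.seed(as.integer(seed))
  labels <- as.character(labels)
  if (is.data.frame(folds)) folds <- folds$fold
  # permute within fold: preserves the balanced fold composition (every
  # fold keeps both classes) while breaking any label-feature association
  perms <- purrr::map(seq_len(n_perm), function(i) {
    out <- labels
    for (f in unique(folds)) {
      idx <- which(folds == f)
      out[idx] <- out[sample(idx)]
    }
    out
  })
  purrr::map_dfr(seq_len(n_perm), function(i) {
    fit <- fit_stacked_classifier(features, perms[[i]], folds, cost = cost)
    out <- tibble::tibble(perm = i, accuracy = fit$accuracy)
    for (m in names(fit$metric_accuracy)) {
      out[[paste0("accuracy_", m)]] <- fit$metric_accuracy[[m]]
    }
    out
  })
}

#' Operational eye-metric presence criterion
#'
#' A metric is designated *present* when its first-level out-of-fold
#' accuracy exceeds the 95th percentile of its permuted-label null.
#'
#' @param fit A `stacked_fit`.
#' @param null Tibble from [permutation_null()] on the same data.
#' @return Tibble with `metric`, `accuracy`, `null_q95`, `present`.
#' @export
eye_metric_presence <- function(fit, null) {
  stopifnot(inherits(fit, "stacked_fit"))
  mets <- names(fit$metric_accuracy)
  purrr::map_dfr(mets, function(m) {
    q <- stats::quantile(null[[paste0("accuracy_", m)]], 0.95, names = FALSE)
    tibble::tibble(metric = m, accuracy = fit$metric_accuracy[[m]],
                   null_q95 = q, present = fit$metric_accuracy[[m]] > q)
  })
}
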