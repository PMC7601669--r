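# Feature-set definitions shared by the classification functions.
feature_columns <- function(feature_set) {
  if (length(feature_set) == 1L && feature_set %in% c("two", "five")) {
    switch(feature_set,
           two = c("rel_blockade", "dwell_s"),
           five = c("rel_blockade", "dwell_s", "auc", "left_slope",
                    "right_slope"))
  } else {
    feature_set
  }
}

#' Standardize feature columns
#'
#' Centers and scales each column to zero mean and unit variance. When
#' `center`/`scale` are supplied (statistics of a training partition) they
#' are applied unchanged, so held-out data never leaks into the scaling.
#'
#' @param x Numeric matrix or data frame of features.
#' @param center,scale Optional per-column statistics from a training set;
#'   computed from `x` when `NULL`.
#' @return List with `x` (standardized matrix), `center`, `scale`.
#' @export
standardize_features <- function(x, center = NULL, scale = NULL) {
  m <- as.matrix(x)
  if (is.null(center)) center <- colMeans(m)
  if (is.null(scale)) {
    scale <- apply(m, 2L, stats::sd)
    flat <- which(scale == 0 | !is.finite(scale))
    if (length(flat)) {
      stop_domain("constant feature(s): ",
                  paste(colnames(m)[flat], collapse = ", "))
    }
  }
  list(x = sweep(sweep(m, 2L, center, "-"), 2L, scale, "/"),
       center = center, scale = scale)
}

# Stratified fold assignment, balanced within each class.
make_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        stop_domain(sprintf(
          "class '%s' has %d events, fewer than %d folds; use fewer folds",
          cl, length(idx), k))
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

# Mean inner-CV accuracy of one (cost, gamma) cell on the training subset.
inner_cv_accuracy <- function(m, y, cost, gamma, kernel, inner_folds, seed) {
  fold <- make_folds(y, inner_folds, seed)
  acc <- numeric(inner_folds)
  for (k in seq_len(inner_folds)) {
    tr <- fold != k
    std <- standardize_features(m[tr, , drop = FALSE])
    fit <- e1071::svm(std$x, y[tr], kernel = kernel, cost = cost,
                      gamma = gamma, scale = FALSE)
    te <- standardize_features(m[!tr, , drop = FALSE],
                               center = std$center, scale = std$scale)
    acc[k] <- mean(stats::predict(fit, te$x) == y[!tr])
  }
  mean(acc)
}

#' Cross-validated SVM classification of event features
#'
#' Stratified k-fold cross-validation of a support vector machine (RBF kernel
#' by default, one-vs-one for multi-class). Within each outer fold the cost
#' and kernel-width hyperparameters are chosen by a nested grid search on the
#' training part only, features are standardized with training-fold
#' statistics only, and the report aggregates the out-of-fold predictions.
#' Deterministic for a fixed seed.
#'
#' @param table Feature table with a label per row.
#' @param labels Class labels (character/factor), one per row of `table`.
#' @param feature_set `"two"` (`rel_blockade`, `dwell_s`), `"five"` (adds
#'   `auc`, `left_slope`, `right_slope`), or a character vector of column
#'   names.
#' @param folds Outer cross-validation folds. Default 5.
#' @param seed Integer seed fixing fold assignment and the nested search.
#' @param cost_grid,gamma_grid Hyperparameter grids (gamma ignored by the
#'   linear kernel).
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param inner_folds Folds of the nested grid search. Default 3.
#' @param fold_id Optional externally supplied fold assignment (used by
#'   [compare_feature_sets()] to pair runs on identical folds).
#' @return Object of class `classification_report`: list with `confusion`
#'   (true x predicted counts), `accuracy`, `per_class_recall`,
#'   `feature_set`, `folds`, `seed`, `n`, and `predictions`.
#' @export
train_eval_svm <- function(table, labels, feature_set = "five", folds = 5,
                           seed = 1L, cost_grid = c(1, 10, 100),
                           gamma_grid = c(0.05, 0.2, 0.8),
                           kernel = c("radial", "linear"), inner_folds = 3,
                           fold_id = NULL) {
  kernel <- match.arg(kernel)
  cols <- feature_columns(feature_set)
  stopifnot(all(cols %in% names(table)))
  y <- factor(as.character(labels))
  if (nlevels(y) < 2L) stop_domain("need at least 2 distinct labels")
  m <- as.matrix(table[cols])
  if (any(!is.finite(m))) stop_domain("non-finite feature values")
  if (is.null(fold_id)) fold_id <- make_folds(y, folds, seed)
  if (kernel == "linear") gamma_grid <- gamma_grid[1L]
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)

  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (k in sort(unique(fold_id))) {
    tr <- fold_id != k
    ytr <- y[tr]
    mtr <- m[tr, , drop = FALSE]
    score <- vapply(seq_len(nrow(grid)), function(g) {
      inner_cv_accuracy(mtr, ytr, grid$cost[g], grid$gamma[g], kernel,
                        inner_folds, seed + 100L * k)
    }, numeric(1))
    best <- grid[which.max(score), ] # ties: first grid cell
    std <- standardize_features(mtr)
    fit <- e1071::svm(std$x, ytr, kernel = kernel, cost = best$cost,
                      gamma = best$gamma, scale = FALSE)
    te <- standardize_features(m[!tr, , drop = FALSE],
                               center = std$center, scale = std$scale)
    pred[!tr] <- stats::predict(fit, te$x)
  }

  confusion <- table(true = y, predicted = pred)
  acc <- sum(diag(confusion)) / sum(confusion)
  recall <- diag(confusion) / rowSums(confusion)
  structure(list(confusion = unclass(confusion), accuracy = acc,
                 per_class_recall = recall,
                 feature_set = paste(cols, collapse = ","),
                 folds = folds, seed = seed, n = length(y),
                 predictions = pred),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("SVM cross-validated report (%d folds, n = %d)\n", x$folds, x$n))
  cat("features:", x$feature_set, "\n")
  cat(sprintf("accuracy: %.1f%%\n", 100 * x$accuracy))
  cat("per-class recall:",
      paste(sprintf("%s %.1f%%", names(x$per_class_recall),
                    100 * x$per_class_recall), collapse = ", "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Paired two- vs five-feature SVM comparison
#'
#' Runs [train_eval_svm()] with the two classical features (relative
#' blockade, dwell time) and with all five features on *identical* fold
#' assignments, so the accuracy difference is a paired comparison.
#'
#' @param table Feature table.
#' @param labels Class labels, one per row.
#' @param folds,seed,... Passed to [train_eval_svm()].
#' @return Object of class `feature_set_comparison`: list with `two`, `five`
#'   (classification reports) and `accuracy_gain` (five minus two, in
#'   percentage points).
#' @export
compare_feature_sets <- function(table, labels, folds = 5, seed = 1L, ...) {
  fold_id <- make_folds(labels, folds, seed)
  two <- train_eval_svm(table, labels, feature_set = "two", folds = folds,
                        seed = seed, fold_id = fold_id, ...)
  five <- train_eval_svm(table, labels, feature_set = "five", folds = folds,
                         seed = seed, fold_id = fold_id, ...)
  structure(list(two = two, five = five,
                 accuracy_gain = 100 * (five$accuracy - two$accuracy)),
            class = "feature_set_comparison")
}

#' @export
print.feature_set_comparison <- function(x, ...) {
  cat(sprintf("two features:  %.1f%%\nfive features: %.1f%%\ngain: %+.1f points\n",
              100 * x$two$accuracy, 100 * x$five$accuracy, x$accuracy_gain))
  invisible(x)
}
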