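#' Build a confusion matrix (rows = predicted, columns = actual)
#'
#' @param actual,predicted Character vectors of equal length.
#' @param labels Optional ordered label set; defaults to the sorted union.
#' @return Integer matrix of class `confusion_matrix` with predicted classes
#'   on the rows and actual classes on the columns.
#' @export
confusion_matrix <- function(actual, predicted, labels = NULL) {
  if (is.null(labels)) labels <- sort(unique(c(actual, predicted)))
  cm <- table(factor(predicted, levels = labels),
              factor(actual, levels = labels))
  cm <- unclass(as.matrix(cm))
  dimnames(cm) <- list(predicted = labels, actual = labels)
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Per-class and macro metrics from a confusion matrix
#'
#' Each class is scored one-versus-rest: with `TP` the diagonal entry, `FP`
#' the rest of its predicted row, `FN` the rest of its actual column and
#' `TN` everything else,
#' accuracy = (TP+TN)/(TP+FP+FN+TN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F-measure = 2TP/(2TP+FP+FN).
#' Macro values are unweighted means over classes; the overall (micro)
#' accuracy, trace over total, is reported alongside. A zero-denominator
#' metric is reported as 0 and flagged degenerate so macro averages stay
#' defined.
#'
#' @param cm A matrix with predicted classes on rows, actual on columns
#'   (see [confusion_matrix()]).
#' @return A list of class `metrics_report` with `per_class` (tibble),
#'   `macro` (named numeric: accuracy, precision, recall, f_measure),
#'   `micro_accuracy`, `confusion` and `n`.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (length(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  labels <- rownames(cm)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(cm)))
  total <- sum(cm)
  rows <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[i, ]) - tp
    fn <- sum(cm[, i]) - tp
    tn <- total - tp - fp - fn
    ratio <- function(num, den) if (den == 0) 0 else num / den
    tibble::tibble(
      label = labels[i],
      accuracy = ratio(tp + tn, total),
      precision = ratio(tp, tp + fp),
      recall = ratio(tp, tp + fn),
      f_measure = ratio(2 * tp, 2 * tp + fp + fn),
      degenerate = (tp + fp == 0) | (tp + fn == 0) | (2 * tp + fp + fn == 0)
    )
  })
  per_class <- do.call(rbind, rows)
  macro <- colMeans(per_class[, c("accuracy", "precision", "recall",
                                  "f_measure")])
  structure(list(per_class = per_class,
                 macro = macro,
                 micro_accuracy = if (total == 0) 0 else
                   sum(diag(cm)) / total,
                 confusion = cm,
                 n = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics over", x$n, "instances,", nrow(x$per_class), "classes\n")
  cat(sprintf("  macro: accuracy %.4f  precision %.4f  recall %.4f  F %.4f\n",
              x$macro[["accuracy"]], x$macro[["precision"]],
              x$macro[["recall"]], x$macro[["f_measure"]]))
  cat(sprintf("  overall (micro) accuracy %.4f\n", x$micro_accuracy))
  invisible(x)
}

#' Fit the full recognition pipeline on a training set
#'
#' Builds the SIA from the training sequences, de-noises them, chooses the
#' number of time clusters (elbow method when `cfg$k == "auto"`) and fits
#' k-means on the (bt, et) points.
#'
#' @param train A `casas_activities` tibble of raw (not yet de-noised)
#'   training instances.
#' @param cfg A [recognition_config()].
#' @param seed Integer seed for the clustering restarts.
#' @return List of class `adl_recognizer`: `sia`, `train` (de-noised),
#'   `model`, `cfg`.
#' @export
fit_recognizer <- function(train, cfg = recognition_config(), seed = 1L) {
  sia <- build_sia(train)
  train_dn <- denoise_activities(train, sia, w = cfg$w_threshold,
                                 dedup = cfg$dedup)
  pts <- time_points(train_dn)
  k <- cfg$k
  if (identical(k, "auto")) {
    num <- length(unique(train$label))
    if (num < 3) {
      k <- max(1L, num)
    } else {
      k <- select_k(pts, num, seed = seed)
    }
  }
  k <- min(as.integer(k), nrow(unique(pts)))
  model <- fit_kmeans(pts, k, seed = seed)
  structure(list(sia = sia, train = train_dn, model = model, cfg = cfg),
            class = "adl_recognizer")
}

#' Predict labels for raw activity instances
#'
#' @param object An `adl_recognizer` from [fit_recognizer()].
#' @param newdata A `casas_activities` tibble of raw instances.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.adl_recognizer <- function(object, newdata, ...) {
  dn <- denoise_activities(newdata, object$sia, w = object$cfg$w_threshold,
                           dedup = object$cfg$dedup)
  vapply(seq_len(nrow(dn)), function(i) {
    recognize(object$train, object$model, dn[i, ], object$cfg)$label
  }, character(1))
}

#' Stratified k-fold cross-validation of the recognition pipeline
#'
#' Splits the instances into `folds` label-stratified folds with a fixed
#' seed. For each fold the SIA is rebuilt from the training portion only
#' (no label leakage), both portions are de-noised with it, clustering is
#' fitted on the training portion, and every test instance is recognised.
#' The final macro metrics are the mean over folds, as in the evaluation
#' protocol the method was designed for; the pooled confusion matrix over
#' all folds is reported as well.
#'
#' @param activities A `casas_activities` tibble of labelled raw instances.
#' @param cfg A [recognition_config()].
#' @param folds Number of folds (default 5).
#' @param seed Integer seed (fold assignment and clustering restarts).
#' @return A list of class `cv_report`: `macro` (named numeric, mean over
#'   folds), `micro_accuracy` (mean over folds), `pooled` (a
#'   `metrics_report` on the pooled confusion matrix), `per_fold` (list of
#'   `metrics_report`), `fold` (integer fold id per instance, `NA` =
#'   training-only), `folds`, `seed`.
#' @details Classes with fewer instances than folds degrade gracefully:
#'   their members land in as many folds as they have instances (warning).
#'   A single-instance class is kept in training only, with a warning.
#' @export
cross_validate <- function(activities, cfg = recognition_config(),
                           folds = 5L, seed = 1L) {
  n <- nrow(activities)
  stopifnot(n >= folds)
  fold <- assign_folds(activities$label, folds, seed)
  labels <- sort(unique(activities$label))
  per_fold <- vector("list", folds)
  pooled <- matrix(0L, length(labels), length(labels),
                   dimnames = list(predicted = labels, actual = labels))
  for (f in seq_len(folds)) {
    test_idx <- which(fold == f)
    if (length(test_idx) == 0) next
    train <- activities[setdiff(seq_len(n), test_idx), , drop = FALSE]
    test <- activities[test_idx, , drop = FALSE]
    rec <- fit_recognizer(train, cfg, seed = seed + f)
    pred <- predict(rec, test)
    cm <- confusion_matrix(test$label, pred, labels = labels)
    pooled <- pooled + cm
    per_fold[[f]] <- metrics_from_confusion(cm)
  }
  used <- !vapply(per_fold, is.null, logical(1))
  macro_mat <- do.call(rbind, lapply(per_fold[used], `[[`, "macro"))
  structure(list(
    macro = colMeans(macro_mat),
    micro_accuracy = mean(vapply(per_fold[used], `[[`, numeric(1),
                                 "micro_accuracy")),
    pooled = metrics_from_confusion(pooled),
    per_fold = per_fold,
    fold = fold, folds = folds, seed = seed
  ), class = "cv_report")
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin starting from a rotating fold. Classes smaller than the fold
# count occupy fewer folds (warning); singletons stay in training (NA).
assign_folds <- function(labels, folds, seed) {
  fold <- rep(NA_integer_, length(labels))
  withr::with_seed(seed, {
    for (lab in sort(unique(labels))) {
      idx <- which(labels == lab)
      if (length(idx) == 1) {
        warning("class '", lab, "' has a single instance; kept in training ",
                "only", call. = FALSE)
        next
      }
      if (length(idx) < folds) {
        warning("class '", lab, "' has fewer instances (", length(idx),
                ") than folds (", folds, "); stratification degraded",
                call. = FALSE)
      }
      idx <- sample(idx)
      fold[idx] <- ((seq_along(idx) - 1L) %% folds) + 1L
    }
  })
  fold
}

#' @export
print.cv_report <- function(x, ...) {
  cat(x$folds, "fold cross-validation (seed ", x$seed, ")\n", sep = "")
  cat(sprintf(
    "  mean over folds: accuracy %.4f  precision %.4f  recall %.4f  F %.4f\n",
    x$macro[["accuracy"]], x$macro[["precision"]], x$macro[["recall"]],
    x$macro[["f_measure"]]))
  cat(sprintf("  mean overall (micro) accuracy %.4f\n", x$micro_accuracy))
  invisible(x)
}
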