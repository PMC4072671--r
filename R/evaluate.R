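# Evaluation: confusion counts, the Sn/Sp/Acc/coverage/MCC suite, ROC/AUC,
# stratified five-fold cross-validation and the multi-class confusion
# matrix.

#' Confusion counts at a decision threshold
#'
#' A score greater than or equal to the threshold is counted as a positive
#' prediction (scores exactly at the threshold are positive).
#'
#' @param scores Numeric decision scores, one per example.
#' @param labels Logical true-class labels (`TRUE` = positive).
#' @param threshold Decision threshold (default 0).
#' @return A `confusion_counts` list with integers `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0) {
  stopifnot(length(scores) == length(labels))
  if (!length(scores)) stop("empty input", call. = FALSE)
  labels <- as.logical(labels)
  pred <- scores >= threshold
  structure(list(TP = sum(pred & labels), FP = sum(pred & !labels),
                 TN = sum(!pred & !labels), FN = sum(!pred & labels)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$TP, x$FP, x$TN, x$FN, x$TP + x$FP + x$TN + x$FN))
  invisible(x)
}

#' Threshold-dependent performance metrics
#'
#' Sensitivity = 100*TP/(TP+FN), specificity = 100*TN/(TN+FP), accuracy =
#' 100*(TP+TN)/total and the Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Coverage (the
#' fraction of true class members recovered) is numerically identical to
#' sensitivity and reported under both names. When any factor of the MCC
#' denominator is zero the MCC is defined as 0, the random-prediction
#' value. A class absent from the evaluated examples yields `NaN` for the
#' corresponding rate.
#'
#' @param counts A [confusion_counts()] object.
#' @return A `metric_set` list: `sensitivity`, `specificity`, `accuracy`,
#'   `coverage` (percentages) and `mcc`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  total <- tp + fp + tn + fn
  if (total == 0) stop("no evaluated examples", call. = FALSE)
  sn <- 100 * tp / (tp + fn)
  sp <- 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / total
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  structure(list(sensitivity = sn, specificity = sp, accuracy = acc,
                 coverage = sn, mcc = mcc),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("Sn=%.2f%% Sp=%.2f%% Acc=%.2f%% MCC=%.3f%s\n",
              x$sensitivity, x$specificity, x$accuracy, x$mcc,
              if (!is.null(x$auc)) sprintf(" AUC=%.3f", x$auc) else ""))
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Sweeps the decision threshold over all distinct score values, records the
#' true- and false-positive proportions and integrates by the trapezoidal
#' rule. The resulting AUC equals the rank statistic
#' P(score+ > score-) + 0.5 P(tie).
#'
#' @param scores Numeric decision scores.
#' @param labels Logical true labels; both classes must be present.
#' @return A list with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC analysis needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # cumulative counts at each distinct threshold (ties collapse together)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(!l)[last_of_tie]
  points <- data.frame(threshold = c(Inf, s[last_of_tie]),
                       fpr = c(0, fp / n_neg),
                       tpr = c(0, tp / n_pos))
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  list(points = points, auc = auc)
}

#' Build a stratified cross-validation plan
#'
#' Assigns every sequence to one of `n_folds` folds. With stratification
#' (the default) fold sizes within each class differ by at most one, which
#' keeps small classes represented in every fold.
#'
#' @param labels Class label per sequence.
#' @param ids Sequence ids (names for the fold assignment); defaults to
#'   names of `labels` or indices.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @param stratified Stratify by class label (default `TRUE`).
#' @return A `cv_plan`: list with `fold` (named integer vector), `n_folds`,
#'   `seed`, `stratified`.
#' @export
cv_plan <- function(labels, ids = NULL, n_folds = 5L, seed = 1L,
                    stratified = TRUE) {
  labels <- as.character(labels)
  if (is.null(ids)) ids <- names(labels) %||% as.character(seq_along(labels))
  stopifnot(length(ids) == length(labels), n_folds >= 2L)
  set.seed(seed)
  fold <- integer(length(labels))
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
    }
  } else {
    fold <- sample(rep(seq_len(n_folds), length.out = length(labels)))
  }
  names(fold) <- ids
  structure(list(fold = fold, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), stratified = stratified),
            class = "cv_plan")
}

#' Stratified k-fold cross-validation of the one-vs-rest models
#'
#' For every class, runs `n_folds` train/test cycles with that class as the
#' positive set and the union of the remaining classes as the negative set.
#' Per-fold sensitivity, specificity, accuracy, coverage, MCC (at decision
#' threshold `threshold`) and ROC-AUC are computed on the held-out fold and
#' averaged arithmetically across folds (the default). `average = "pooled"`
#' instead pools counts and scores over folds before computing the metrics,
#' a diagnostic mode.
#'
#' @param x Feature matrix (rows = sequences, rownames = ids).
#' @param labels Class label per row.
#' @param spec An [svm_spec()] used for every fold model.
#' @param plan A [cv_plan()]; built from `labels` with `seed` if omitted.
#' @param classes Class set to evaluate; all must have at least `n_folds`
#'   members.
#' @param threshold Decision threshold for the confusion counts.
#' @param average `"per_fold"` (arithmetic mean of per-fold metrics) or
#'   `"pooled"`.
#' @param seed Seed used when `plan` is omitted.
#' @return A `cv_result`: list with `folds` (long data frame of per-class,
#'   per-fold metrics), `per_class` (one averaged row per class) and
#'   `overall` (across-class means).
#' @export
cross_validate <- function(x, labels, spec = svm_spec(), plan = NULL,
                           classes = transporter_classes, threshold = 0,
                           average = c("per_fold", "pooled"), seed = 1L) {
  average <- match.arg(average)
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (is.null(plan)) plan <- cv_plan(labels, rownames(x), seed = seed)
  fold <- plan$fold
  k <- plan$n_folds
  sizes <- table(factor(labels, levels = classes))
  small <- names(sizes)[sizes < k]
  if (length(small)) {
    stop("class(es) smaller than the fold count: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (cl in classes) {
    y <- labels == cl
    pooled_scores <- numeric(0); pooled_y <- logical(0)
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- train_binary(x[tr, , drop = FALSE], y[tr], spec)
      sc <- decision_scores(m, x[!tr, , drop = FALSE])
      met <- classification_metrics(confusion_counts(sc, y[!tr], threshold))
      auc <- roc_auc(sc, y[!tr])$auc
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, fold = f, sensitivity = met$sensitivity,
        specificity = met$specificity, accuracy = met$accuracy,
        coverage = met$coverage, mcc = met$mcc, auc = auc)
      pooled_scores <- c(pooled_scores, sc)
      pooled_y <- c(pooled_y, y[!tr])
    }
    if (average == "pooled") {
      met <- classification_metrics(
        confusion_counts(pooled_scores, pooled_y, threshold))
      auc <- roc_auc(pooled_scores, pooled_y)$auc
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, fold = NA_integer_, sensitivity = met$sensitivity,
        specificity = met$specificity, accuracy = met$accuracy,
        coverage = met$coverage, mcc = met$mcc, auc = auc)
    }
  }
  folds_df <- do.call(rbind, rows)
  metric_cols <- c("sensitivity", "specificity", "accuracy", "coverage",
                   "mcc", "auc")
  per_class <- if (average == "per_fold") {
    stats::aggregate(folds_df[metric_cols],
                     by = list(class = folds_df$class), FUN = mean)
  } else {
    folds_df[is.na(folds_df$fold), c("class", metric_cols)]
  }
  per_class <- per_class[match(classes, per_class$class), ]
  rownames(per_class) <- NULL
  overall <- colMeans(per_class[metric_cols])
  structure(list(folds = folds_df[!is.na(folds_df$fold), ],
                 per_class = per_class, overall = overall,
                 plan = plan, average = average, threshold = threshold),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, digits = 2, ...) {
  cat(sprintf("%d-fold cross-validation (%s averaging)\n",
              x$plan$n_folds, x$average))
  tab <- x$per_class
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat("Across-class average:\n")
  print(round(x$overall, digits))
  invisible(x)
}

#' Multi-class confusion matrix of an ensemble
#'
#' @param ensemble A fitted `ovr_ensemble`.
#' @param x Feature matrix.
#' @param labels True class label per row.
#' @return An 8 x 8 table, rows = true class, columns = argmax-predicted
#'   class; row sums equal the class sizes.
#' @export
confusion_matrix_multiclass <- function(ensemble, x, labels) {
  pred <- predict(ensemble, x, type = "class")
  table(true = factor(as.character(labels), levels = ensemble$classes),
        predicted = factor(pred, levels = ensemble$classes))
}

#' Write a cross-validation metric table as TSV
#'
#' One row per class plus an `average` row, with the Sn/Sp/Acc/MCC/AUC
#' columns.
#'
#' @param cv A `cv_result`.
#' @param path Output path.
#' @export
write_metrics_tsv <- function(cv, path) {
  stopifnot(inherits(cv, "cv_result"))
  tab <- cv$per_class
  avg <- data.frame(class = "average", t(cv$overall), check.names = FALSE)
  tab <- rbind(tab, avg)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
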