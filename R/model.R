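# One-vs-rest RBF-SVM layer. Each of the eight classes gets a binary SVM
# trained with that class positive and the union of the other seven
# negative; the ensemble prediction is the argmax of the eight decision
# scores. Feature vectors are consumed exactly as the encoders produce
# them: no internal re-scaling.

#' SVM training configuration
#'
#' Mirrors the tunables of an SVM-Light-style RBF classifier: the kernel,
#' the RBF width `gamma` (searched over `gamma_grid`, by default 7
#' log-spaced points covering 1e-5..10), the positive-class cost factor
#' (SVM-Light's `-j`, searched over 1..4) and the shared regularization
#' constant C.
#'
#' @param kernel `"rbf"` (default), `"linear"` or `"polynomial"`.
#' @param gamma RBF width; positive.
#' @param cost_factor Weight on positive-class training errors; positive.
#' @param cost Shared regularization constant C; positive.
#' @param gamma_grid,cost_factor_grid Candidate grids for [grid_search()].
#' @param seed Integer seed controlling fold assignment during tuning.
#' @return An object of class `svm_spec`.
#' @export
svm_spec <- function(kernel = c("rbf", "linear", "polynomial"),
                     gamma = 0.01, cost_factor = 1, cost = 1,
                     gamma_grid = 10^seq(-5, 1, length.out = 7),
                     cost_factor_grid = 1:4, seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(gamma > 0, cost_factor > 0, cost > 0,
            length(gamma_grid) >= 1L, all(gamma_grid > 0),
            length(cost_factor_grid) >= 1L, all(cost_factor_grid > 0))
  structure(list(kernel = kernel, gamma = gamma, cost_factor = cost_factor,
                 cost = cost, gamma_grid = gamma_grid,
                 cost_factor_grid = cost_factor_grid,
                 seed = as.integer(seed)),
            class = "svm_spec")
}

#' @export
print.svm_spec <- function(x, ...) {
  cat(sprintf("<svm_spec> kernel=%s gamma=%g cost_factor=%g C=%g\n",
              x$kernel, x$gamma, x$cost_factor, x$cost))
  invisible(x)
}

e1071_kernel <- function(k) switch(k, rbf = "radial", k)

#' Train a binary SVM
#'
#' @param x Numeric feature matrix (rows = examples).
#' @param y Logical vector: `TRUE` for the positive (target) class.
#' @param spec An [svm_spec()].
#' @return A `binary_svm` whose decision score is positive on the target
#'   class side of the boundary.
#' @export
train_binary <- function(x, y, spec = svm_spec()) {
  x <- as.matrix(x)
  y <- as.logical(y)
  if (nrow(x) != length(y)) {
    stop("feature matrix rows (", nrow(x), ") and labels (", length(y),
         ") differ in length", call. = FALSE)
  }
  if (sum(y) < 2L || sum(!y) < 2L) {
    stop("need at least 2 examples of each label to train", call. = FALSE)
  }
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("pos", "neg"))
  fit <- e1071::svm(x = x, y = yf, kernel = e1071_kernel(spec$kernel),
                    gamma = spec$gamma, cost = spec$cost,
                    class.weights = c(pos = spec$cost_factor, neg = 1),
                    scale = FALSE)
  # libsvm signs decision values by the first label it encounters; fix the
  # orientation once so that score > 0 always means the positive class
  dv <- attr(stats::predict(fit, x[1:2, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  flip <- !startsWith(colnames(dv)[1], "pos")
  structure(list(fit = fit, flip = flip, spec = spec, dim = ncol(x),
                 feature_names = colnames(x)),
            class = "binary_svm")
}

#' Decision scores of a binary SVM
#'
#' @param model A `binary_svm`.
#' @param x Feature matrix with the model's training dimension.
#' @return Numeric vector of signed decision scores (positive = target
#'   class).
#' @export
decision_scores <- function(model, x) {
  stopifnot(inherits(model, "binary_svm"))
  x <- as.matrix(x)
  if (ncol(x) != model$dim) {
    stop("feature dimension ", ncol(x), " does not match model dimension ",
         model$dim, call. = FALSE)
  }
  dv <- attr(stats::predict(model$fit, x, decision.values = TRUE),
             "decision.values")
  s <- as.numeric(dv[, 1])
  if (model$flip) s <- -s
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  fold
}

#' Grid search over gamma and cost factor
#'
#' Scores every (gamma, cost_factor) pair by mean stratified k-fold CV
#' accuracy and returns the spec updated with the best pair. Ties are broken
#' deterministically towards smaller gamma, then smaller cost factor. A grid
#' point whose training folds degenerate to a single class is scored as
#' failed and excluded; if every point fails, an error is raised.
#'
#' @inheritParams train_binary
#' @param folds Number of CV folds (>= 2).
#' @return The input [svm_spec()] with `gamma` and `cost_factor` set to the
#'   winning pair; the CV accuracy table is attached as attribute
#'   `"cv_table"`.
#' @export
grid_search <- function(x, y, spec = svm_spec(), folds = 5L) {
  x <- as.matrix(x)
  y <- as.logical(y)
  stopifnot(folds >= 2L)
  fold <- stratified_folds(y, folds, spec$seed)
  grid <- expand.grid(gamma = sort(spec$gamma_grid),
                      cost_factor = sort(spec$cost_factor_grid))
  grid$accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    trial <- spec
    trial$gamma <- grid$gamma[g]
    trial$cost_factor <- grid$cost_factor[g]
    acc <- numeric(folds)
    ok <- TRUE
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || sum(y[tr]) < 2L || sum(!y[tr]) < 2L) {
        ok <- FALSE
        break
      }
      m <- train_binary(x[tr, , drop = FALSE], y[tr], trial)
      pred <- decision_scores(m, x[!tr, , drop = FALSE]) >= 0
      acc[f] <- mean(pred == y[!tr])
    }
    if (ok) grid$accuracy[g] <- mean(acc)
  }
  if (all(is.na(grid$accuracy))) {
    stop("every grid point failed cross-validation", call. = FALSE)
  }
  # grid is sorted by (cost_factor, gamma) blocks; order() with ties keeps
  # the smallest gamma then smallest cost_factor among maxima
  ord <- order(-grid$accuracy, grid$gamma, grid$cost_factor)
  best <- grid[ord[1], ]
  out <- spec
  out$gamma <- best$gamma
  out$cost_factor <- best$cost_factor
  attr(out, "cv_table") <- grid
  out
}

#' Fit the one-vs-rest transporter ensemble
#'
#' The central fitting function: trains one binary RBF-SVM per class, each
#' with that class as the positive set and the union of the remaining
#' classes as the negative set, all sharing the same encoder and feature
#' matrix.
#'
#' @param x Feature matrix from [encode_sequences()] (rows = sequences).
#' @param labels Class label per row; every class in `classes` must be
#'   present with at least 2 members.
#' @param spec An [svm_spec()] applied to every member model.
#' @param classes Class set; defaults to the eight transporter classes.
#' @param tune If `TRUE`, run [grid_search()] per class before the final
#'   fit.
#' @return An object of class `ovr_ensemble` with `print`, `summary` and
#'   `predict` methods.
#' @examples
#' \donttest{
#' ds <- make_dataset(n_per_class = 12, separation = 0.2, seed = 7)
#' x <- encode_sequences(ds$sequences, "AAC")
#' fit <- train_ovr(x, ds$manifest$class_label)
#' predict(fit, x[1:3, ])
#' }
#' @export
train_ovr <- function(x, labels, spec = svm_spec(),
                      classes = transporter_classes, tune = FALSE) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  missing_ <- setdiff(classes, labels)
  if (length(missing_)) {
    stop("class(es) missing from training labels: ",
         paste(missing_, collapse = ", "), call. = FALSE)
  }
  models <- lapply(classes, function(cl) {
    y <- labels == cl
    s <- if (tune) grid_search(x, y, spec) else spec
    train_binary(x, y, s)
  })
  names(models) <- classes
  structure(list(models = models, classes = classes,
                 encoder = attr(x, "encoder") %||% NA_character_,
                 dim = ncol(x), feature_names = colnames(x),
                 spec = spec, n_train = nrow(x),
                 class_sizes = table(factor(labels, levels = classes))),
            class = "ovr_ensemble")
}

#' @export
print.ovr_ensemble <- function(x, ...) {
  cat(sprintf(
    "One-vs-rest SVM ensemble: %d classes, encoder %s, %d features, %d training sequences\n",
    length(x$classes), x$encoder, x$dim, x$n_train))
  invisible(x)
}

#' @export
summary.ovr_ensemble <- function(object, ...) {
  print(object)
  cat("Classes (positive-set sizes):\n")
  print(object$class_sizes)
  cat(sprintf("Kernel %s, gamma %g, cost factor %g, C %g\n",
              object$spec$kernel, object$spec$gamma,
              object$spec$cost_factor, object$spec$cost))
  nsv <- vapply(object$models, function(m) nrow(m$fit$SV), 0L)
  cat("Support vectors per class model:\n")
  print(nsv)
  invisible(object)
}

#' Predict class membership from an ensemble
#'
#' @param object An `ovr_ensemble`.
#' @param newdata Feature matrix with the ensemble's feature dimension.
#' @param type `"class"` for the argmax label, `"scores"` for the n x 8
#'   decision-score matrix, or `"both"` for a data frame holding both. Ties
#'   in the argmax are broken by the fixed class order.
#' @param ... Unused.
#' @export
predict.ovr_ensemble <- function(object, newdata,
                                 type = c("class", "scores", "both"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$dim) {
    stop("feature dimension ", ncol(newdata),
         " does not match ensemble dimension ", object$dim, call. = FALSE)
  }
  enc <- attr(newdata, "encoder")
  if (!is.null(enc) && !is.na(object$encoder) && !identical(enc, object$encoder)) {
    stop("encoder mismatch: features are ", enc, " but the model was trained on ",
         object$encoder, call. = FALSE)
  }
  scores <- vapply(object$models, decision_scores, numeric(nrow(newdata)),
                   x = newdata)
  if (nrow(newdata) == 1L) scores <- matrix(scores, 1L,
                                            dimnames = list(NULL, object$classes))
  rownames(scores) <- rownames(newdata)
  cls <- object$classes[max.col(scores, ties.method = "first")]
  switch(type,
         class  = cls,
         scores = scores,
         both   = data.frame(sequence_id = rownames(newdata) %||%
                               seq_len(nrow(newdata)),
                             predicted = cls, scores, check.names = FALSE))
}

#' Transporter vs non-transporter call
#'
#' A sequence is called a transporter when the non-transporter member
#' model's decision score falls below `threshold`: the sequence does not
#' look like the control class. Raising the threshold can only move calls
#' from non-transporter to transporter.
#'
#' @param ensemble An `ovr_ensemble` containing a `non_transporter` model.
#' @param x Feature matrix.
#' @param threshold Decision-score cutoff (default 0, the SVM boundary).
#' @return Logical vector: `TRUE` = predicted transporter.
#' @export
predict_transporter <- function(ensemble, x, threshold = 0) {
  stopifnot(inherits(ensemble, "ovr_ensemble"))
  if (!"non_transporter" %in% ensemble$classes) {
    stop("ensemble has no non_transporter model", call. = FALSE)
  }
  decision_scores(ensemble$models[["non_transporter"]], as.matrix(x)) < threshold
}

model_format <- "transpec_ovr_ensemble"
model_version <- 1L

#' Persist / restore an ensemble
#'
#' The archive stores a format tag and version alongside the fitted models,
#' encoder tag and component names; loading a file with a different format
#' or version fails explicitly rather than silently misreading.
#'
#' @param ensemble An `ovr_ensemble`.
#' @param path Archive path.
#' @export
save_model <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ovr_ensemble"))
  saveRDS(list(format = model_format, version = model_version,
               ensemble = ensemble), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read model archive ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, model_format)) {
    stop("file ", path, " is not a transpec model archive", call. = FALSE)
  }
  if (!identical(obj$version, model_version)) {
    stop("model archive version ", obj$version,
         " not supported (expected ", model_version, ")", call. = FALSE)
  }
  obj$ensemble
}
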