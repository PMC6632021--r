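#' Confusion matrix from truth and prediction
#'
#' @param truth,pred Vectors of labels.
#' @param positive Label counted as positive.
#' @return A `confusion_matrix` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_matrix <- function(truth, pred, positive) {
  stopifnot(length(truth) == length(pred))
  p <- truth == positive
  structure(list(tp = sum(p & pred == positive),
                 fp = sum(!p & pred == positive),
                 tn = sum(!p & pred != positive),
                 fn = sum(p & pred != positive)),
            class = "confusion_matrix")
}

#' Evaluation metrics from a confusion matrix
#'
#' Recall (sensitivity) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, false
#' positive rate `1 - specificity`, precision `TP/(TP+FP)`, F-score
#' (harmonic mean of recall and precision) and accuracy
#' `(TP+TN)/total`. A metric whose denominator is zero is reported `NA`;
#' the others are unaffected.
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector `recall, specificity, fpr, precision,
#'   f_score, accuracy` (fractions in \[0, 1\]).
#' @export
metrics <- function(cm) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  recall <- div(cm$tp, cm$tp + cm$fn)
  specificity <- div(cm$tn, cm$tn + cm$fp)
  precision <- div(cm$tp, cm$tp + cm$fp)
  f <- f_score(recall, precision)
  acc <- div(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn)
  c(recall = recall, specificity = specificity,
    fpr = if (is.na(specificity)) NA_real_ else 1 - specificity,
    precision = precision, f_score = f, accuracy = acc)
}

#' F-score from recall and precision
#'
#' Harmonic mean `2 * recall * precision / (recall + precision)`; accepts
#' fractions or percentages (the result is on the same scale).
#'
#' @param recall,precision Recall and precision.
#' @return The F-score.
#' @export
f_score <- function(recall, precision) {
  if (any(is.na(c(recall, precision))) || recall + precision == 0)
    return(NA_real_)
  2 * recall * precision / (recall + precision)
}

#' Model specification for the binary classifiers
#'
#' `svm_poly3` is a support vector machine with a third-degree polynomial
#' kernel (the degree is fixed); `knn` is a k-nearest-neighbor classifier
#' with Euclidean distance. Features are standardized with training-set
#' statistics in both cases.
#'
#' @param kind `"svm_poly3"` or `"knn"`.
#' @param cost SVM regularization constant (default 1).
#' @param k Number of neighbors for KNN (default 5).
#' @return A `model_spec` object.
#' @export
model_spec <- function(kind = c("svm_poly3", "knn"), cost = 1, k = 5L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, cost = cost, k = as.integer(k), degree = 3L),
            class = "model_spec")
}

#' Train a binary classifier
#'
#' Standardizes the features with training-data statistics (stored in the
#' model and re-applied at prediction time, so no test information leaks
#' into the scaling), then fits the model named by `spec`. Training is
#' deterministic for a fixed seed.
#'
#' @param features Numeric matrix or data frame of feature columns.
#' @param labels Vector with exactly two distinct labels.
#' @param spec A [model_spec()].
#' @param seed RNG seed.
#' @return An `mi_model` with a [predict.mi_model()] method.
#' @export
train_model <- function(features, labels, spec = model_spec(), seed = 1L) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("training labels must contain exactly two classes")
  if (nrow(x) != length(y)) stop("feature/label length mismatch")
  center <- colMeans(x)
  scale_ <- apply(x, 2L, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- scale(x, center = center, scale = scale_)
  fit <- if (spec$kind == "svm_poly3") {
    with_seed(seed, e1071::svm(
      xs, y, kernel = "polynomial", degree = spec$degree, coef0 = 1,
      cost = spec$cost, scale = FALSE
    ))
  } else {
    list(train = xs, y = y)  # KNN is a lazy learner
  }
  structure(list(spec = spec, fit = fit, center = center, scale = scale_,
                 levels = levels(y), seed = as.integer(seed)),
            class = "mi_model")
}

#' Predict labels with a trained model
#'
#' @param object An `mi_model` from [train_model()].
#' @param newdata Feature matrix/data frame with the training columns.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.mi_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (ncol(x) != length(object$center))
    stop("feature dimension mismatch at predict time")
  xs <- scale(x, center = object$center, scale = object$scale)
  if (object$spec$kind == "svm_poly3") {
    as.character(predict(object$fit, xs))
  } else {
    as.character(with_seed(object$seed,
      class::knn(object$fit$train, xs, object$fit$y, k = object$spec$k)))
  }
}

#' Stratified k-fold cross-validation
#'
#' Partitions the samples into `k` folds, stratified by class and shuffled
#' under the seed, so that every sample is tested exactly once. For each
#' fold the model is trained on the remaining folds (standardization
#' statistics computed on the training folds only) and evaluated on the
#' held-out fold; the six metrics are reported per fold with their mean
#' and standard deviation.
#'
#' @param features Feature matrix/data frame.
#' @param labels Binary label vector.
#' @param positive Label counted as positive for the metrics.
#' @param spec A [model_spec()].
#' @param k Number of folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @return A `cv_result` list with `folds` (per-fold metrics data frame),
#'   `mean`, `sd`, `fold_assignment`.
#' @export
cross_validate <- function(features, labels, positive, spec = model_spec(),
                           k = 5L, seed = 1L) {
  x <- as.matrix(features)
  y <- as.character(labels)
  n <- nrow(x)
  if (min(table(y)) < k) stop("too few samples per class for ", k, " folds")
  fold <- integer(n)
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  per_fold <- lapply(seq_len(k), function(fi) {
    tr <- fold != fi
    m <- train_model(x[tr, , drop = FALSE], y[tr], spec, seed = seed)
    pred <- predict(m, x[!tr, , drop = FALSE])
    metrics(confusion_matrix(y[!tr], pred, positive))
  })
  folds <- as.data.frame(do.call(rbind, per_fold))
  folds$fold <- seq_len(k)
  structure(list(folds = folds,
                 mean = colMeans(folds[setdiff(names(folds), "fold")]),
                 sd = apply(folds[setdiff(names(folds), "fold")], 2L, sd),
                 fold_assignment = fold),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds\n", nrow(x$folds)))
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(m, 4))
  invisible(x)
}

#' Run the two binary MI detection tasks
#'
#' Task A (STEMI) discriminates normal from ST-elevation beats, task B
#' (NSTEMI) normal from T-inversion beats. Both use the same feature set —
#' time-domain, frequency-domain and joint (t,f) features from the chosen
#' TFD — and the same stratified five-fold protocol.
#'
#' @param dataset A `labeled_dataset` containing the `NORMAL`,
#'   `ST_ELEVATION` and `T_INVERSION` classes.
#' @param spec A [model_spec()].
#' @param tfd_kind TFD used for the joint features.
#' @param k Folds (default 5).
#' @param seed RNG seed.
#' @param features Optional precomputed [extract_features()] result (to
#'   reuse across model specs); computed from `dataset` when `NULL`.
#' @return List with `stemi` and `nstemi` [cross_validate()] results and
#'   the feature data frame.
#' @export
run_tasks <- function(dataset, spec = model_spec(), tfd_kind = "embd",
                      k = 5L, seed = 1L, features = NULL) {
  need <- c("NORMAL", "ST_ELEVATION", "T_INVERSION")
  if (!all(need %in% unique(dataset$label)))
    stop("dataset must contain NORMAL, ST_ELEVATION and T_INVERSION classes")
  if (is.null(features)) features <- extract_features(dataset, tfd_kind)
  run_one <- function(abnormal) {
    sel <- features$label %in% c("NORMAL", abnormal)
    fx <- features[sel, setdiff(names(features), "label"), drop = FALSE]
    fx <- fx[, vapply(fx, function(v) all(is.finite(v)), TRUE), drop = FALSE]
    cross_validate(fx, features$label[sel], positive = abnormal,
                   spec = spec, k = k, seed = seed)
  }
  list(stemi = run_one("ST_ELEVATION"), nstemi = run_one("T_INVERSION"),
       features = features)
}
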