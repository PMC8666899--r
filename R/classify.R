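#' Train the linear apnoea/false-alarm classifier
#'
#' Fits a linear soft-margin SVM separating true central apnoeas from
#' artefactually low-amplitude false alarms in the five-dimensional feature
#' space of [extract_features()].  Features are standardised (stored means
#' and scales are part of the model, so predictions are invariant to affine
#' rescaling of any feature column).  The fit is deterministic given the
#' data.
#'
#' @param features Data frame or matrix of numeric features (no missing
#'   values).
#' @param labels Factor or character vector with exactly two classes; the
#'   first level (or `"apnoea"` if present) is the positive class.
#' @param cost Soft-margin regularisation constant C.
#' @param standardise Standardise features before fitting (recommended;
#'   kept as a switch for diagnostic use).
#' @return A `linear_svm_model`: `weights`, `bias`, `feature_means`,
#'   `feature_scales`, `cost`, `levels` (positive class first).  The
#'   decision value for a standardised feature vector z is
#'   `sum(weights * z) + bias`; positive values predict the positive class.
#' @export
train_classifier <- function(features, labels, cost = 1,
                             standardise = TRUE) {
  x <- as.matrix(features)
  if (any(!is.finite(x)))
    stopf("train_classifier: features contain missing/non-finite values")
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2L)
    stopf("train_classifier: need exactly two classes, got %d",
          nlevels(labels))
  pos <- if ("apnoea" %in% levels(labels)) "apnoea" else levels(labels)[1L]
  neg <- setdiff(levels(labels), pos)
  mu <- if (standardise) colMeans(x) else rep(0, ncol(x))
  sc <- if (standardise) apply(x, 2, stats::sd) else rep(1, ncol(x))
  sc[!is.finite(sc) | sc == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sc, "/")
  fit <- e1071::svm(x = z, y = labels, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # align the sign convention: decision > 0 must predict the positive class
  pred <- predict(fit, z)
  dec <- drop(z %*% w) + b
  agree <- mean((dec > 0) == (pred == pos))
  if (agree < 0.5) { w <- -w; b <- -b }
  structure(list(weights = w, bias = b, feature_means = mu,
                 feature_scales = sc, cost = cost,
                 feature_names = colnames(x), levels = c(pos, neg)),
            class = "linear_svm_model")
}

#' Predict with a linear apnoea classifier
#'
#' @param object A `linear_svm_model` from [train_classifier()].
#' @param newdata Data frame or matrix of features.  Rows with missing
#'   features are classified `"indeterminate"` rather than forced into a
#'   class.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.linear_svm_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(x)))
    x <- x[, object$feature_names, drop = FALSE]
  ok <- apply(x, 1, function(r) all(is.finite(r)))
  out <- rep("indeterminate", nrow(x))
  if (any(ok)) {
    z <- sweep(sweep(x[ok, , drop = FALSE], 2, object$feature_means), 2,
               object$feature_scales, "/")
    dec <- drop(z %*% object$weights) + object$bias
    out[ok] <- ifelse(dec > 0, object$levels[1L], object$levels[2L])
  }
  out
}

#' @export
print.linear_svm_model <- function(x, ...) {
  cat("linear_svm_model (", paste(x$levels, collapse = " vs "), "), C = ",
      x$cost, "\n", sep = "")
  w <- x$weights
  names(w) <- x$feature_names
  print(round(w, 4))
  cat("bias:", round(x$bias, 4), "\n")
  invisible(x)
}

#' Binary classification metrics
#'
#' Accuracy, false-positive rate, false-negative rate and Matthews
#' correlation coefficient, with the confusion-matrix counts.  MCC is
#' reported as 0 when any marginal is zero (the undefined-denominator
#' convention).
#'
#' @param predicted,actual Vectors of equal length with two classes.
#' @param positive The positive-class label (default `"apnoea"` if present,
#'   else the first level of `actual`).
#' @return A `classification_metrics` list: `accuracy`, `fpr`, `fnr`,
#'   `mcc`, `tp`, `fp`, `fn`, `tn`.
#' @export
compute_metrics <- function(predicted, actual, positive = NULL) {
  predicted <- as.character(predicted)
  actual <- as.character(actual)
  if (length(predicted) != length(actual))
    stopf("compute_metrics: length mismatch")
  if (is.null(positive))
    positive <- if ("apnoea" %in% actual) "apnoea" else sort(unique(actual))[1L]
  tp <- sum(predicted == positive & actual == positive)
  fp <- sum(predicted == positive & actual != positive)
  fn <- sum(predicted != positive & actual == positive)
  tn <- sum(predicted != positive & actual != positive)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  structure(list(accuracy = (tp + tn) / length(actual),
                 fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
                 fnr = if (fn + tp > 0) fn / (fn + tp) else NA_real_,
                 mcc = mcc, tp = tp, fp = fp, fn = fn, tn = tn),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f | FPR %.3f | FNR %.3f | MCC %.3f (tp %d fp %d fn %d tn %d)\n",
              x$accuracy, x$fpr, x$fnr, x$mcc, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject, trains the classifier on all other subjects and
#' predicts the held-out subject's episodes; metrics are pooled over all
#' held-out predictions, so no within-subject leakage can inflate them.
#'
#' @param features Data frame/matrix of features.
#' @param labels Two-class labels.
#' @param subject_ids Subject identifier per row (>= 2 distinct subjects).
#' @param cost,standardise Passed to [train_classifier()].
#' @return A `classification_metrics` object; the pooled predictions are
#'   attached as attribute `"predictions"`.
#' @export
loso_cv <- function(features, labels, subject_ids, cost = 1,
                    standardise = TRUE) {
  subject_ids <- as.character(subject_ids)
  subs <- unique(subject_ids)
  if (length(subs) < 2L)
    stopf("loso_cv: need at least 2 subjects, got %d", length(subs))
  labels <- as.character(labels)
  pred <- character(length(labels))
  for (s in subs) {
    held <- subject_ids == s
    model <- train_classifier(features[!held, , drop = FALSE],
                              labels[!held], cost = cost,
                              standardise = standardise)
    pred[held] <- predict(model, features[held, , drop = FALSE])
  }
  m <- compute_metrics(pred, labels)
  attr(m, "predictions") <- pred
  m
}

#' Save / load a linear SVM model as plain JSON
#'
#' The model is stored as readable parameters (weights, bias, means,
#' scales), never as an opaque binary.
#'
#' @param model A `linear_svm_model`.
#' @param path File path.
#' @return `write_model`: `path`, invisibly.  `read_model`: the model.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$weights <- as.numeric(m$weights)
  structure(m, class = "linear_svm_model")
}
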