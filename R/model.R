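# Classic fit/predict interface over the classifiers.

#' Train a lesion classifier on labeled LOI samples
#'
#' Fits the feature standardizer on the supplied training samples and then
#' either the k-NN rule (k-NN is lazy; "fitting" stores the standardized
#' training set) or the Gaussian-kernel SVM.
#'
#' @param samples A `rel_cohort` or data frame of labeled samples (see
#'   [generate_cohort()] / [read_features_csv()]).
#' @param model `"knn"` (default) or `"svm"`.
#' @param feature_set `"nine"` or `"seven"`.
#' @param k,C,gamma Hyperparameters; see [knn_predict()] and [svm_fit()].
#' @param positive_class Positive label for reported metrics; default
#'   `"ABSCESS"`.
#' @return An object of class `rel_model` with `predict`, `print` and
#'   `summary` methods.
#' @export
rel_train <- function(samples, model = c("knn", "svm"),
                      feature_set = "nine", k = 5L, C = 1, gamma = NULL,
                      positive_class = "ABSCESS") {
  model <- match.arg(model)
  x <- sample_matrix(samples, feature_set)
  std <- fit_standardizer(x)
  xs <- apply_standardizer(std, x)
  fit <- if (model == "svm") svm_fit(xs, samples$label, C = C, gamma = gamma)
  else NULL
  structure(list(model = model, standardizer = std, feature_set = feature_set,
                 train_x = xs, train_y = as.character(samples$label),
                 train_subjects = unique(samples$subject_id),
                 k = as.integer(k), C = C, gamma = gamma, svm = fit,
                 positive_class = positive_class),
            class = "rel_model")
}

#' Predict lesion classes for new samples
#'
#' @param object A fitted [rel_train()] model.
#' @param newdata Data frame with the feature columns (raw, unstandardized;
#'   the training standardizer is applied).
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.rel_model <- function(object, newdata, ...) {
  xs <- apply_standardizer(object$standardizer,
                           sample_matrix(newdata, object$feature_set))
  if (object$model == "knn")
    knn_predict(object$train_x, object$train_y, xs, k = object$k)
  else svm_predict(object$svm, xs)
}

#' @export
print.rel_model <- function(x, ...) {
  cat(sprintf("REL classifier (%s, %s-feature set): %d training lines from %d subjects\n",
              x$model, x$feature_set, length(x$train_y),
              length(x$train_subjects)))
  if (x$model == "knn") cat(sprintf("  k = %d (Euclidean)\n", x$k))
  else print(x$svm)
  invisible(x)
}

#' Summarize a fitted classifier
#'
#' Reports the training ("resubstitution") confusion matrix and metrics.
#'
#' @param object A fitted `rel_model`.
#' @param ... Unused.
#' @export
summary.rel_model <- function(object, ...) {
  pred <- if (object$model == "knn")
    knn_predict(object$train_x, object$train_y, object$train_x, k = object$k)
  else svm_predict(object$svm, object$train_x)
  cm <- confusion(object$train_y, pred, object$positive_class)
  out <- list(model = object, train_confusion = cm,
              train_metrics = metrics(cm))
  class(out) <- "summary.rel_model"
  out
}

#' @export
print.summary.rel_model <- function(x, ...) {
  print(x$model)
  print(x$train_confusion)
  m <- x$train_metrics
  cat(sprintf("training Acc = %.3f, TPR = %.3f, FNR = %.3f\n",
              m["accuracy"], m["tpr"], m["fnr"]))
  invisible(x)
}
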