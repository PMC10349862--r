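# Subject-level splitting, standardization, k-NN and Gaussian-kernel SVM,
# grouped cross-validation, and confusion-matrix metrics.
#
# Splits and folds always partition SUBJECTS, never lines: all five LOIs of a
# patient travel together, so no subject leaks between train and test.

CLASS_LEVELS <- c("ABSCESS", "GBM")

sample_matrix <- function(df, feature_set = "nine") {
  cols <- feature_names(feature_set)
  m <- as.matrix(df[cols])
  if (any(!is.finite(m)))
    stopf("non-finite feature values; did you mix feature sets?")
  storage.mode(m) <- "double"
  m
}

#' Split a cohort into train and test subjects
#'
#' Subjects (not lines) are partitioned, stratified by class with rounding to
#' the nearest integer per class; every LOI sample follows its subject.
#'
#' @param cohort A `rel_cohort` or data frame with `subject_id`, `label`.
#' @param train_fraction Fraction of subjects per class used for training;
#'   default 0.75.
#' @param seed Integer seed for the subject shuffle.
#' @return List of class `data_split`: `train_subjects`, `test_subjects`,
#'   `train`, `test` (row subsets of `cohort`).
#' @export
split_cohort <- function(cohort, train_fraction = 0.75, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("'train_fraction' must be in (0, 1)")
  subj <- unique(cohort[c("subject_id", "label")])
  for (lab in unique(subj$label))
    if (sum(subj$label == lab) < 2L)
      stopf("class '%s' has fewer than 2 subjects", lab)
  train_subjects <- character()
  with_seed(derive_seed(seed, "split"), {
    for (lab in sort(unique(subj$label))) {
      ids <- subj$subject_id[subj$label == lab]
      n_train <- round(train_fraction * length(ids))
      n_train <- min(max(n_train, 1L), length(ids) - 1L)
      train_subjects <- c(train_subjects, sample(ids, n_train))
    }
  })
  test_subjects <- setdiff(subj$subject_id, train_subjects)
  structure(list(train_subjects = sort(train_subjects),
                 test_subjects = sort(test_subjects),
                 train = cohort[cohort$subject_id %in% train_subjects, ,
                                drop = FALSE],
                 test = cohort[cohort$subject_id %in% test_subjects, ,
                               drop = FALSE]),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("subject-level split: %d train subjects (%d lines) / %d test subjects (%d lines)\n",
              length(x$train_subjects), nrow(x$train),
              length(x$test_subjects), nrow(x$test)))
  invisible(x)
}

#' Fit / apply a feature standardizer
#'
#' Per-feature location (mean) and scale (sample SD, denominator n-1)
#' estimated on the training samples only, so transformed training features
#' have mean 0 and unit sample variance. Zero-variance features are dropped
#' with a warning. Transformed matrices carry a `standardized` flag;
#' re-applying a standardizer to already-standardized input is an error (a
#' guard against silently double-scaling).
#'
#' @param x Numeric feature matrix (rows = samples), `>= 2` rows.
#' @return For `fit_standardizer`, an object of class `standardizer`; for
#'   `apply_standardizer`, the transformed matrix (columns restricted to the
#'   retained features).
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stopf("standardizer needs >= 2 training samples")
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  keep <- scale > 0
  if (!all(keep))
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(colnames(x)[!keep], collapse = ", ")))
  structure(list(center = center[keep], scale = scale[keep],
                 features = colnames(x)[keep]),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param std A fitted `standardizer`.
#' @export
apply_standardizer <- function(std, x) {
  stopifnot(inherits(std, "standardizer"))
  if (isTRUE(attr(x, "standardized")))
    stopf("input is already standardized; refusing to scale twice")
  x <- as.matrix(x)
  if (!is.null(colnames(x))) {
    missing <- setdiff(std$features, colnames(x))
    if (length(missing))
      stopf("missing feature column(s): %s", paste(missing, collapse = ", "))
    x <- x[, std$features, drop = FALSE]
  }
  out <- sweep(sweep(x, 2L, std$center), 2L, std$scale, "/")
  attr(out, "standardized") <- TRUE
  out
}

#' k-nearest-neighbours prediction
#'
#' Euclidean distances in the standardized feature space; majority vote among
#' the `k` nearest training samples. Vote ties are broken by the label of the
#' single nearest neighbour; distance ties by the lower training-sample
#' index. Fully deterministic.
#'
#' @param train_x Standardized training feature matrix.
#' @param train_y Training labels (character or factor).
#' @param query_x Standardized query matrix (rows = queries).
#' @param k Number of neighbours, `1 <= k <= nrow(train_x)`; default 5.
#' @return Character vector of predicted labels.
#' @export
knn_predict <- function(train_x, train_y, query_x, k = 5L) {
  train_x <- as.matrix(train_x); query_x <- as.matrix(query_x)
  train_y <- as.character(train_y)
  k <- as.integer(k)
  if (k < 1L || k > nrow(train_x))
    stopf("k must be in [1, %d]", nrow(train_x))
  tsq <- rowSums(train_x^2)
  out <- character(nrow(query_x))
  for (q in seq_len(nrow(query_x))) {
    d2 <- tsq - 2 * as.numeric(train_x %*% query_x[q, ]) +
      sum(query_x[q, ]^2)
    ord <- order(d2, seq_along(d2))          # distance ties -> lower index
    nn <- ord[seq_len(k)]
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    out[q] <- if (length(top) == 1L) top else train_y[nn[1]]
  }
  out
}

#' Fit / predict a soft-margin Gaussian-kernel SVM
#'
#' Solves the soft-margin dual with kernel
#' `k(x, x') = exp(-gamma * ||x - x'||^2)` (via the libsvm solver in e1071);
#' the decision is `sign(sum_i alpha_i y_i k(x_i, q) + bias)`. The returned
#' model exposes the dual quantities (support vectors, `alpha_i y_i`
#' multipliers, bias) and is checked against the dual constraints
#' `0 <= alpha_i <= C` and `sum_i alpha_i y_i = 0` (tolerance 1e-6).
#'
#' @param train_x Standardized training feature matrix.
#' @param train_y Training labels; both classes must be present.
#' @param C Box constraint; default 1.
#' @param gamma Kernel width; default `1 / (n_features * mean feature
#'   variance)` on the training matrix.
#' @return An object of class `svm_model`.
#' @export
svm_fit <- function(train_x, train_y, C = 1, gamma = NULL) {
  train_x <- as.matrix(train_x)
  y <- factor(as.character(train_y), levels = CLASS_LEVELS)
  if (length(unique(stats::na.omit(as.character(y)))) < 2L)
    stopf("SVM training needs both classes present")
  gamma <- gamma %||% (1 / (ncol(train_x) * mean(apply(train_x, 2L, stats::var))))
  fit <- e1071::svm(x = train_x, y = y, scale = FALSE, kernel = "radial",
                    gamma = gamma, cost = C)
  ay <- as.numeric(fit$coefs)                # alpha_i * y_i
  if (abs(sum(ay)) > 1e-6)
    stopf("SVM dual constraint sum(alpha_i y_i) = 0 violated (%.3g)", sum(ay))
  if (any(abs(ay) > C + 1e-6))
    stopf("SVM dual constraint alpha_i <= C violated")
  structure(list(fit = fit, support_vectors = fit$SV,
                 multipliers = abs(ay), labels = sign(ay),
                 bias = -fit$rho, gamma = gamma, C = C),
            class = "svm_model")
}

#' @rdname svm_fit
#' @param model A fitted `svm_model`.
#' @param query_x Standardized query matrix.
#' @export
svm_predict <- function(model, query_x) {
  stopifnot(inherits(model, "svm_model"))
  as.character(stats::predict(model$fit, as.matrix(query_x)))
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("Gaussian-kernel SVM: %d support vectors, C = %g, gamma = %.4g\n",
              nrow(x$support_vectors), x$C, x$gamma))
  invisible(x)
}

#' Confusion matrix and performance metrics
#'
#' `metrics()` returns accuracy `Acc = (TP + TN) / (TP + TN + FP + FN)`, the
#' true positive rate (sensitivity) `TPR = TP / (TP + FN)` and the false
#' negative rate `FNR = 1 - TPR`, so `TPR + FNR = 1` holds exactly.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param positive_class Label counted as positive; default `"ABSCESS"` (the
#'   clinically urgent class).
#' @return For `confusion()`, an object of class `confusion_matrix` with
#'   counts `tp`, `tn`, `fp`, `fn`; for `metrics()`, a named numeric
#'   `c(accuracy, tpr, fnr)`.
#' @export
confusion <- function(truth, predicted, positive_class = "ABSCESS") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stopf("label vectors differ in length")
  pos_t <- truth == positive_class; pos_p <- predicted == positive_class
  structure(list(tp = sum(pos_t & pos_p), tn = sum(!pos_t & !pos_p),
                 fp = sum(!pos_t & pos_p), fn = sum(pos_t & !pos_p),
                 positive_class = positive_class),
            class = "confusion_matrix")
}

#' @rdname confusion
#' @param cm A `confusion_matrix`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0L) stopf("empty confusion matrix")
  if (cm$tp + cm$fn == 0L)
    stopf("TPR undefined: no positive samples (TP + FN = 0)")
  tpr <- cm$tp / (cm$tp + cm$fn)
  c(accuracy = (cm$tp + cm$tn) / total, tpr = tpr, fnr = 1 - tpr)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix (positive = %s):\n", x$positive_class))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(t(m)[c(1, 2), ])
  invisible(x)
}

add_confusion <- function(a, b) {
  structure(list(tp = a$tp + b$tp, tn = a$tn + b$tn, fp = a$fp + b$fp,
                 fn = a$fn + b$fn, positive_class = a$positive_class),
            class = "confusion_matrix")
}

# Grouped, stratified fold assignment: within each class subjects are
# shuffled and dealt round-robin into folds.
make_folds <- function(subj, n_folds, seed) {
  folds <- stats::setNames(rep(NA_integer_, nrow(subj)), subj$subject_id)
  with_seed(derive_seed(seed, "cv"), {
    for (lab in sort(unique(subj$label))) {
      ids <- sample(subj$subject_id[subj$label == lab])
      folds[ids] <- rep_len(seq_len(n_folds), length(ids))
    }
  })
  folds
}

#' Grouped, stratified k-fold cross-validation
#'
#' Folds partition subjects (never lines), stratified by class. The
#' standardizer is refit inside every fold on that fold's training subjects
#' only. The pooled confusion matrix sums the fold matrices, so its total is
#' the number of samples.
#'
#' @param samples A `rel_cohort` or data frame of labeled samples.
#' @param model `"knn"` or `"svm"`.
#' @param n_folds Number of folds; default 5. Each class needs at least
#'   `n_folds` subjects.
#' @param k,C,gamma Model hyperparameters (see [knn_predict()], [svm_fit()]).
#' @param feature_set `"nine"` or `"seven"`.
#' @param positive_class Positive label for the confusion matrix.
#' @param seed Seed for the fold shuffle.
#' @return List of class `cv_result`: `fold_confusions`, `pooled`
#'   (a `confusion_matrix`), `pooled_metrics`, `fold_assignment`.
#' @export
cross_validate <- function(samples, model = c("knn", "svm"), n_folds = 5L,
                           k = 5L, C = 1, gamma = NULL,
                           feature_set = "nine",
                           positive_class = "ABSCESS", seed = 1L) {
  model <- match.arg(model)
  subj <- unique(samples[c("subject_id", "label")])
  if (length(unique(subj$label)) < 2L)
    stopf("cross-validation needs both classes present")
  for (lab in unique(subj$label))
    if (sum(subj$label == lab) < n_folds)
      stopf("class '%s' has fewer subjects (%d) than folds (%d)",
            lab, sum(subj$label == lab), n_folds)
  folds <- make_folds(subj, n_folds, seed)
  fold_cms <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    held <- names(folds)[folds == f]
    tr <- samples[!(samples$subject_id %in% held), , drop = FALSE]
    te <- samples[samples$subject_id %in% held, , drop = FALSE]
    std <- fit_standardizer(sample_matrix(tr, feature_set))
    trx <- apply_standardizer(std, sample_matrix(tr, feature_set))
    tex <- apply_standardizer(std, sample_matrix(te, feature_set))
    pred <- if (model == "knn") knn_predict(trx, tr$label, tex, k = k)
    else svm_predict(svm_fit(trx, tr$label, C = C, gamma = gamma), tex)
    fold_cms[[f]] <- confusion(te$label, pred, positive_class)
  }
  pooled <- Reduce(add_confusion, fold_cms)
  structure(list(fold_confusions = fold_cms, pooled = pooled,
                 pooled_metrics = metrics(pooled), fold_assignment = folds,
                 model = model, n_folds = n_folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  m <- x$pooled_metrics
  cat(sprintf("%d-fold grouped CV (%s): pooled Acc = %.3f, TPR = %.3f, FNR = %.3f\n",
              x$n_folds, x$model, m["accuracy"], m["tpr"], m["fnr"]))
  invisible(x)
}

#' Hyperparameter grid search with no-improvement stopping
#'
#' Walks an ordered grid of candidate hyperparameter values, scoring each by
#' grouped CV accuracy, and stops once `patience` consecutive candidates fail
#' to improve the best score by more than `tol` — a cross-validation analogue
#' of early stopping for these non-iterative learners.
#'
#' @param samples Labeled samples.
#' @param model `"knn"` (grid over `k`) or `"svm"` (grid over `C`).
#' @param grid Candidate values in evaluation order; defaults
#'   `k in {1,3,5,7,9}` / `C in {0.1, 1, 10, 100}`.
#' @param patience Consecutive non-improvements tolerated; default 1.
#' @param tol Minimum accuracy improvement that counts; default 0.
#' @param ... Passed to [cross_validate()].
#' @return List: `best` (the selected value), `scores` (named accuracies for
#'   evaluated candidates).
#' @export
tune_model <- function(samples, model = c("knn", "svm"), grid = NULL,
                       patience = 1L, tol = 0, ...) {
  model <- match.arg(model)
  grid <- grid %||% if (model == "knn") c(1L, 3L, 5L, 7L, 9L)
  else c(0.1, 1, 10, 100)
  best <- -Inf; best_val <- grid[1]; bad <- 0L
  scores <- numeric(0)
  for (g in grid) {
    cv <- if (model == "knn") cross_validate(samples, "knn", k = g, ...)
    else cross_validate(samples, "svm", C = g, ...)
    acc <- cv$pooled_metrics[["accuracy"]]
    scores[as.character(g)] <- acc
    if (acc > best + tol) { best <- acc; best_val <- g; bad <- 0L }
    else {
      bad <- bad + 1L
      if (bad > patience) break
    }
  }
  list(best = best_val, scores = scores)
}
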