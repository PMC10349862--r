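make_feature_df <- function(x, labels, subjects = NULL) {
  df <- as.data.frame(x)
  names(df) <- feature_names("nine")[seq_len(ncol(x))]
  for (nm in setdiff(feature_names("nine"), names(df))) df[[nm]] <- 0
  df$label <- labels
  df$subject_id <- subjects %||% sprintf("s%03d", seq_len(nrow(df)))
  df$loi_id <- "loi1"
  df
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("subject-level split reproduces the 150/50 line design", {
  co <- generate_cohort(cohort_spec(seed = 2))
  sp <- split_cohort(co, 0.75, seed = 2)
  expect_length(sp$train_subjects, 30L)
  expect_equal(nrow(sp$train), 150L)
  expect_equal(nrow(sp$test), 50L)
  expect_length(intersect(sp$train_subjects, sp$test_subjects), 0L)
  # stratified rounding: 26 GBM -> 19-20 train, 14 abscess -> 10-11
  subj <- unique(sp$train[c("subject_id", "label")])
  expect_true(sum(subj$label == "GBM") %in% 19:20)
  expect_true(sum(subj$label == "ABSCESS") %in% 10:11)
  # every line follows its subject
  expect_true(all(sp$train$subject_id %in% sp$train_subjects))
  expect_true(all(sp$test$subject_id %in% sp$test_subjects))
  expect_error(split_cohort(generate_cohort(
    cohort_spec(n_gbm = 1, n_abscess = 5, seed = 1))), "fewer than 2")
})

test_that("standardizer centers and scales with n-1, training-estimated", {
  x <- matrix(c(0, 10), ncol = 1, dimnames = list(NULL, "median_T"))
  std <- fit_standardizer(x)
  z <- apply_standardizer(std, x)
  expect_equal(as.numeric(z), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(var(as.numeric(z)), 1)

  set.seed(3)
  tr <- matrix(rnorm(60, 5, 3), 20, 3,
               dimnames = list(NULL, c("median_E", "median_T", "std_E")))
  s2 <- fit_standardizer(tr)
  z2 <- apply_standardizer(s2, tr)
  expect_lt(max(abs(colMeans(z2))), 1e-9)
  expect_equal(unname(apply(z2, 2, var)), rep(1, 3), tolerance = 1e-9)
  # a test value equal to the training mean maps to 0
  q <- matrix(s2$center, 1, dimnames = list(NULL, colnames(tr)))
  expect_lt(max(abs(apply_standardizer(s2, q))), 1e-12)
  # double standardization is rejected
  expect_error(apply_standardizer(s2, z2), "already standardized")
  # zero-variance features are dropped with a warning
  tr0 <- cbind(tr, grad_E_rise = 7)
  expect_warning(s3 <- fit_standardizer(tr0), "zero-variance")
  expect_false("grad_E_rise" %in% s3$features)
})

test_that("k-NN follows the majority/tie-break contract", {
  tr <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  labs <- c("GBM", "GBM", "ABSCESS", "GBM")
  expect_equal(knn_predict(tr, labs, tr[3, , drop = FALSE], k = 1), "ABSCESS")
  q <- matrix(c(0.4, 0.4), 1, 2)
  # 3 nearest of q: (0,0) GBM, (1,0)? distances: pick k=3 -> 2 GBM 1 other
  expect_equal(knn_predict(tr, labs, q, k = 3), "GBM")
  expect_error(knn_predict(tr, labs, q, k = 5), "k must be")
  # k = 1 reproduces training labels when feature vectors are unique
  set.seed(11)
  x <- matrix(rnorm(100), 20, 5)
  y <- sample(c("GBM", "ABSCESS"), 20, TRUE)
  expect_identical(knn_predict(x, y, x, k = 1), y)
})

test_that("k-NN matches the exhaustive-distance oracle on random queries", {
  set.seed(21)
  x <- matrix(rnorm(300), 60, 5)
  y <- sample(c("GBM", "ABSCESS"), 60, TRUE)
  q <- matrix(rnorm(200 * 5), 200, 5)
  for (k in c(1, 3, 5)) {
    mine <- knn_predict(x, y, q, k = k)
    ref <- vapply(seq_len(nrow(q)),
                  function(i) oracle_knn(x, y, q[i, ], k), "")
    expect_identical(mine, ref)
  }
})

test_that("the SVM separates toy problems and honors dual constraints", {
  x1 <- matrix(c(-2, -1.5, 1.5, 2), 4, 1)
  y1 <- c("ABSCESS", "ABSCESS", "GBM", "GBM")
  m1 <- svm_fit(x1, y1, C = 1, gamma = 1)
  expect_identical(svm_predict(m1, x1), y1)
  # XOR needs the Gaussian kernel
  xx <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  yy <- c("GBM", "ABSCESS", "ABSCESS", "GBM")
  m2 <- svm_fit(xx, yy, C = 10, gamma = 1)
  expect_identical(svm_predict(m2, xx), yy)
  expect_lt(abs(sum(m2$multipliers * m2$labels)), 1e-6)
  expect_true(all(m2$multipliers <= 10 + 1e-6))
  expect_error(svm_fit(xx, rep("GBM", 4)), "both classes")
})

test_that("grouped CV holds out each subject exactly once", {
  co <- generate_cohort(cohort_spec(seed = 5))
  sp <- split_cohort(co, seed = 5)
  cv <- cross_validate(sp$train, "knn", n_folds = 5, seed = 5)
  folds <- cv$fold_assignment
  expect_length(folds, 30L)
  expect_true(all(table(folds) == 6L))
  pooled <- cv$pooled
  expect_equal(pooled$tp + pooled$tn + pooled$fp + pooled$fn, nrow(sp$train))
  expect_gte(cv$pooled_metrics[["accuracy"]], 0.9)
  few <- co[co$subject_id %in% c("g01", "g02", "g03", "a01", "a02", "a03"), ]
  expect_error(cross_validate(few, "knn", n_folds = 5), "fewer subjects")
  expect_error(cross_validate(co[co$label == "GBM", ], "knn"), "both classes")
})

test_that("confusion counts and metrics follow their definitions", {
  truth <- c(rep("ABSCESS", 10), rep("GBM", 10))
  pred <- c(rep("ABSCESS", 8), rep("GBM", 2), rep("GBM", 10))
  cm <- confusion(truth, pred, "ABSCESS")
  expect_equal(unclass(cm)[c("tp", "fn", "tn", "fp")],
               list(tp = 8L, fn = 2L, tn = 10L, fp = 0L))
  m <- metrics(cm)
  expect_equal(m[["tpr"]], 0.8)
  expect_equal(m[["fnr"]], 0.2)
  expect_equal(m[["accuracy"]], 0.9)
  perfect <- metrics(confusion(truth, truth, "ABSCESS"))
  expect_identical(perfect[["accuracy"]], 1)
  expect_identical(perfect[["fnr"]], 0)
  expect_error(metrics(confusion(rep("GBM", 3), rep("GBM", 3), "ABSCESS")),
               "TPR undefined")
  set.seed(13)
  t2 <- sample(c("ABSCESS", "GBM"), 100, TRUE)
  p2 <- sample(c("ABSCESS", "GBM"), 100, TRUE)
  cm2 <- confusion(t2, p2, "ABSCESS")
  ref <- oracle_confusion(t2, p2, "ABSCESS")
  expect_equal(c(tp = cm2$tp, tn = cm2$tn, fp = cm2$fp, fn = cm2$fn), ref)
})

test_that("the fitted-model interface trains, predicts and summarizes", {
  co <- generate_cohort(cohort_spec(seed = 6))
  sp <- split_cohort(co, seed = 6)
  for (m in c("knn", "svm")) {
    fit <- rel_train(sp$train, m)
    expect_s3_class(fit, "rel_model")
    pred <- predict(fit, sp$test)
    expect_gte(mean(pred == sp$test$label), 0.85)
    expect_output(print(fit), "REL classifier")
    expect_output(print(summary(fit)), "training Acc")
  }
})

test_that("grid search stops when accuracy stalls", {
  co <- generate_cohort(cohort_spec(n_gbm = 10, n_abscess = 10, seed = 8))
  tuned <- tune_model(co, "knn", grid = c(1L, 3L, 5L, 7L, 9L), seed = 8)
  expect_true(tuned$best %in% c(1L, 3L, 5L, 7L, 9L))
  # separable cohort: accuracy 1 at k = 1, so stopping kicks in early
  expect_lt(length(tuned$scores), 5L)
})
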