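# End-to-end orchestration: simulate (or load) -> sample -> landmarks ->
# features -> group statistics -> train -> evaluate, with one config, a
# reproducibility manifest, and deterministic outputs under a fixed seed.

#' Build a pipeline run configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"load"` (read
#'   maps + LOI annotations, or a ready feature CSV).
#' @param seed Root seed; all stage substreams derive from it.
#' @param n_gbm,n_abscess,lois_per_subject Cohort design for simulate mode
#'   (defaults 26 / 14 / 5, i.e. 200 lines).
#' @param feature_set `"nine"` or `"seven"`.
#' @param models Classifiers to train; subset of `c("knn", "svm")`.
#' @param train_fraction Subject-level train fraction; default 0.75.
#' @param n_folds CV folds; default 5.
#' @param alpha Significance level for the group statistics; default 0.05.
#' @param k,C Hyperparameters for k-NN / SVM.
#' @param features_csv Load mode: path to a feature CSV (skips the imaging
#'   stages).
#' @param map_paths,loi_json,landmarks_json,labels_csv Load mode, imaging
#'   route: per-subject map files, LOI annotations, optional manual
#'   landmarks, and a `subject_id,label` CSV.
#' @param auto_landmarks Load mode: allow automatic landmark detection when
#'   no manual annotation exists; default `TRUE`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "load"), seed = 1L,
                       n_gbm = 26L, n_abscess = 14L, lois_per_subject = 5L,
                       feature_set = "nine", models = c("knn", "svm"),
                       train_fraction = 0.75, n_folds = 5L, alpha = 0.05,
                       k = 5L, C = 1, features_csv = NULL,
                       map_paths = NULL, loi_json = NULL,
                       landmarks_json = NULL, labels_csv = NULL,
                       auto_landmarks = TRUE) {
  mode <- match.arg(mode)
  if (mode == "load" && is.null(features_csv) &&
      (is.null(map_paths) || is.null(loi_json) || is.null(labels_csv)))
    stopf("load mode needs 'features_csv' or 'map_paths' + 'loi_json' + 'labels_csv'")
  structure(list(mode = mode, seed = as.integer(seed), n_gbm = n_gbm,
                 n_abscess = n_abscess, lois_per_subject = lois_per_subject,
                 feature_set = feature_set,
                 models = match.arg(models, several.ok = TRUE),
                 train_fraction = train_fraction, n_folds = n_folds,
                 alpha = alpha, k = k, C = C, features_csv = features_csv,
                 map_paths = map_paths, loi_json = loi_json,
                 landmarks_json = landmarks_json, labels_csv = labels_csv,
                 auto_landmarks = auto_landmarks),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Writes `features.csv`, `stats.csv`, one `eval_<model>.json` per
#' classifier, and `manifest.json` into `out_dir`. Re-running with the same
#' config reproduces every numeric output.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The report bundle, invisibly: `features`, `stats`, `split`,
#'   `evaluations`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  samples <- if (config$mode == "simulate") {
    stage("simulate", generate_cohort(cohort_spec(
      n_gbm = config$n_gbm, n_abscess = config$n_abscess,
      lois_per_subject = config$lois_per_subject, seed = config$seed)))
  } else if (!is.null(config$features_csv)) {
    stage("load", read_features_csv(config$features_csv))
  } else {
    pipeline_load_images(config)
  }

  features_path <- file.path(out_dir, "features.csv")
  stage("features", write_features_csv(samples, features_path))

  stats_tab <- stage("stats", compare_cohort(samples, alpha = config$alpha))
  utils::write.csv(stats_tab, file.path(out_dir, "stats.csv"),
                   row.names = FALSE)

  split <- stage("split", split_cohort(samples, config$train_fraction,
                                       seed = config$seed))
  evals <- list()
  for (m in config$models) {
    ev <- stage(paste0("train_", m), {
      cv <- cross_validate(split$train, m, n_folds = config$n_folds,
                           k = config$k, C = config$C,
                           feature_set = config$feature_set,
                           seed = config$seed)
      fit <- rel_train(split$train, m, feature_set = config$feature_set,
                       k = config$k, C = config$C)
      pred <- predict(fit, split$test)
      cm <- confusion(split$test$label, pred)
      per_class <- vapply(CLASS_LEVELS, function(lab) {
        idx <- split$test$label == lab
        mean(pred[idx] == lab)
      }, 1)
      list(model = m,
           cv = list(pooled = unclass(cv$pooled)[c("tp", "tn", "fp", "fn")],
                     metrics = as.list(cv$pooled_metrics)),
           test = list(confusion = unclass(cm)[c("tp", "tn", "fp", "fn")],
                       metrics = as.list(metrics(cm)),
                       per_class_accuracy = as.list(per_class)))
    })
    evals[[m]] <- ev
    jsonlite::write_json(ev, file.path(out_dir, sprintf("eval_%s.json", m)),
                         auto_unbox = TRUE, digits = NA)
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               null = "null", digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(seed = config$seed,
                   config = unclass(config)[!vapply(unclass(config), is.null,
                                                    TRUE)],
                   config_md5 = unname(tools::md5sum(tmp)),
                   package_version = as.character(
                     utils::packageVersion("relloi")),
                   r_version = R.version.string,
                   n_samples = nrow(samples),
                   n_train = nrow(split$train), n_test = nrow(split$test))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(features = samples, stats = stats_tab, split = split,
                 evaluations = evals, manifest = manifest))
}

# Imaging route of load mode: read each map, sample its LOIs, land landmarks
# (manual JSON wins; otherwise automatic detection if allowed), extract
# features.
pipeline_load_images <- function(config) {
  labels <- stage("load", {
    lab <- utils::read.csv(config$labels_csv, stringsAsFactors = FALSE)
    stats::setNames(lab$label, lab$subject_id)
  })
  lois <- stage("load", read_loi_json(config$loi_json))
  manual <- if (!is.null(config$landmarks_json))
    stage("load", read_landmarks_json(config$landmarks_json)) else list()
  maps <- stage("load", {
    ms <- lapply(config$map_paths, read_adc_map)
    names(ms) <- vapply(config$map_paths, function(p)
      sub("\\.[^.]*$", "", basename(p)), "")
    ms
  })
  rows <- list()
  for (l in lois) {
    map <- maps[[l$subject_id]]
    if (is.null(map))
      stage("sample", stopf("no map for subject '%s'", l$subject_id))
    prof <- stage("sample", sample_loi(map, l))
    lm <- manual[[l$loi_id]]
    if (is.null(lm)) {
      if (!config$auto_landmarks)
        stage("landmarks",
              stopf("no manual landmarks for '%s' and automatic detection is off",
                    l$loi_id))
      lm <- stage("landmarks", detect_landmarks(prof))
    }
    fv <- stage("features", extract_features(prof, lm, config$feature_set))
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = l$subject_id, loi_id = l$loi_id,
      label = unname(labels[l$subject_id]), t(fv), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}
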