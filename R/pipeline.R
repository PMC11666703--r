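# End-to-end orchestration: synthetic study -> preprocessing -> feature
# extraction -> selection -> boosted BP regression (+ BHS grading) ->
# rebalanced hypertension classification (+ ROC/confusion metrics).

#' Pipeline configuration
#'
#' @param synth A [synth_config()] describing the synthetic study.
#' @param filter A [filter_spec()].
#' @param sqi_threshold Minimum S-SQI for [quality_filter()].
#' @param feature_set `"preset"` (curated subsets per target),
#'   `"all"` (every registry feature), or `"demographics"` (age, height,
#'   weight, gender, BMI only).
#' @param base `"gbm"` or `"tree"` base learner for the boosting ensemble.
#' @param rounds Maximum boosting rounds.
#' @param learning_rate Boosting learning rate.
#' @param loss Boosting loss family.
#' @param gbm_nrounds Trees per gradient-boosted base learner fit.
#' @param rebalance_method `"none"`, `"undersample"` or `"smote"`.
#' @param smote_k SMOTE neighbour count.
#' @param test_frac,folds Split specification (0.2 / 5 by default).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            filter = filter_spec(),
                            sqi_threshold = 0,
                            feature_set = c("preset", "all", "demographics"),
                            base = c("gbm", "tree"),
                            rounds = 20,
                            learning_rate = 0.1,
                            loss = "linear",
                            gbm_nrounds = 150,
                            rebalance_method = "smote",
                            smote_k = 3,
                            test_frac = 0.2,
                            folds = 5) {
  feature_set <- match.arg(feature_set)
  base <- match.arg(base)
  assert_that(test_frac > 0 && test_frac < 1, "test_frac must be in (0,1)")
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_base <- function(config) {
  if (config$base == "gbm") base_learner_gbm(nrounds = config$gbm_nrounds)
  else base_learner_tree()
}

pipeline_features <- function(config, target) {
  switch(config$feature_set,
         preset = feature_preset(target),
         all = feature_registry()$name,
         demographics = c("age", "height", "weight", "gender", "bmi"))
}

#' Run the full PPG-to-blood-pressure pipeline
#'
#' Executes, under a single seed: synthetic study generation, band-pass
#' filtering + normalization + S-SQI gating, single-cycle feature
#' extraction, feature selection, AdaBoost.R2 regression of SBP and DBP
#' through the 80/20 + 5-fold harness (with MAE/STD and BHS grading), and
#' hypertension classification on the same split (rebalanced training
#' set, random-forest classifier, confusion metrics + ROC/AUC), plus the
#' regression-thresholding classifier for comparison.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `ppg_run`: `features` (the extracted table),
#'   `regression` (per-target list with `cv`, `report`, `selected`),
#'   `classification` (confusion counts, metrics tibble, `roc`),
#'   `regression_classifier` (thresholded-BP confusion + metrics),
#'   `counts` (per-stage bookkeeping) and `config`.
#' @examples
#' \donttest{
#' run <- run_pipeline(pipeline_config(synth = synth_config(seed = 1,
#'                                                          n_subjects = 40),
#'                                     base = "tree", rounds = 5))
#' glance(run)
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  seed <- config$synth$seed
  ds <- generate_ppg_dataset(config$synth)
  pre <- preprocess_segments(ds$segments, config$filter,
                             config$sqi_threshold)
  feats <- extract_features(pre, ds$subjects)
  assert_that(nrow(feats) >= 20, "too few feature rows survived preprocessing")
  counts <- list(
    n_subjects = nrow(ds$subjects),
    n_segments = nrow(ds$segments),
    quality_log = attr(pre, "rejection_log"),
    n_feature_rows = nrow(feats),
    n_extract_failed = attr(feats, "n_failed")
  )

  regression <- purrr::map(c(sbp = "sbp", dbp = "dbp"), function(target) {
    cols <- intersect(pipeline_features(config, target), names(feats))
    x <- feats[, cols, drop = FALSE]
    keep <- stats::complete.cases(x)
    x <- x[keep, , drop = FALSE]
    y <- feats[[target]][keep]
    base <- pipeline_base(config)
    cv <- cv_harness(
      x, y,
      model_fun = function(d, yy) {
        adaboost_r2(d, yy, base = base, rounds = config$rounds,
                    learning_rate = config$learning_rate,
                    loss = config$loss, seed = seed + 101)
      },
      seed = seed, test_frac = config$test_frac, folds = config$folds)
    list(cv = cv,
         report = regression_report(cv$test$predicted, cv$test$observed),
         selected = cols, keep = keep)
  })

  cls <- classify_hypertension(
    feats, method = config$rebalance_method, k = config$smote_k,
    seed = seed, test_frac = config$test_frac,
    feature_set = pipeline_features(config, "htn"))

  # thresholding the regression test predictions reproduces the
  # classify-from-regression comparison
  sbp_cv <- regression$sbp$cv
  dbp_cv <- regression$dbp$cv
  keep_rows <- which(regression$sbp$keep)
  shared <- intersect(sbp_cv$test_idx, dbp_cv$test_idx)
  sb <- sbp_cv$test$predicted[match(shared, sbp_cv$test_idx)]
  db <- dbp_cv$test$predicted[match(shared, dbp_cv$test_idx)]
  truth <- feats$hypertensive[keep_rows[shared]]
  reg_cls <- NULL
  if (length(shared) >= 5 && any(truth) && any(!truth)) {
    cc <- confusion(truth, label_hypertension(sb, db))
    reg_cls <- list(confusion = cc, metrics = classification_metrics(cc))
  }

  structure(list(features = feats, regression = regression,
                 classification = cls, regression_classifier = reg_cls,
                 counts = counts, config = config),
            class = "ppg_run")
}

#' Hypertension classification with imbalance handling
#'
#' Seeded 80/20 split; the training portion is rebalanced
#' (undersampling or SMOTE, training-set only so no synthetic point leaks
#' into the test set), a random forest is fitted, and the held-out test
#' rows are scored.
#'
#' @param feats Feature table from [extract_features()] including a
#'   `hypertensive` column.
#' @param method,k Rebalancing strategy and SMOTE neighbour count.
#' @param seed Seed for split, rebalance and forest.
#' @param test_frac Held-out fraction.
#' @param feature_set Feature names to use (default: the `"htn"` preset).
#' @return A list of class `htn_result`: `confusion`, `metrics`, `roc`,
#'   `train_balance` (class counts after rebalancing), `test` tibble.
#' @export
classify_hypertension <- function(feats, method = "smote", k = 3, seed = 1,
                                  test_frac = 0.2,
                                  feature_set = feature_preset("htn")) {
  cols <- intersect(feature_set, names(feats))
  x <- feats[, cols, drop = FALSE]
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  y <- feats$hypertensive[keep]
  n <- nrow(x)
  set.seed(seed)
  test_idx <- sort(sample.int(n, round(test_frac * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  reb <- rebalance(x[train_idx, , drop = FALSE], y[train_idx],
                   method = method, k = k, seed = seed + 7)
  set.seed(seed + 13)
  rf <- randomForest::randomForest(
    x = as.data.frame(reb$data), y = factor(reb$labels,
                                            levels = c(FALSE, TRUE)))
  score <- predict(rf, as.data.frame(x[test_idx, , drop = FALSE]),
                   type = "prob")[, "TRUE"]
  pred <- score >= 0.5
  truth <- y[test_idx]
  cc <- confusion(truth, pred)
  structure(list(
    confusion = cc,
    metrics = classification_metrics(cc),
    roc = if (any(truth) && any(!truth)) roc_auc(truth, score) else NULL,
    train_balance = table(reb$labels),
    test = tibble(truth = truth, score = score, predicted = pred),
    model = rf
  ), class = "htn_result")
}

#' @export
print.ppg_run <- function(x, ...) {
  cat("<ppg_run>\n")
  print(glance(x))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `ppg_run`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.ppg_run <- function(x, ...) {
  r <- x$regression
  tibble(
    n_feature_rows = x$counts$n_feature_rows,
    sbp_mae = r$sbp$report$mae, sbp_std = r$sbp$report$std,
    sbp_bhs = r$sbp$report$grade,
    dbp_mae = r$dbp$report$mae, dbp_std = r$dbp$report$std,
    dbp_bhs = r$dbp$report$grade,
    htn_f1 = x$classification$metrics$f1,
    htn_auc = if (!is.null(x$classification$roc))
      x$classification$roc$auc else NA_real_
  )
}

#' @rdname run_pipeline
#' @exportS3Method generics::tidy
tidy.ppg_run <- function(x, ...) {
  bind_rows(
    x$regression$sbp$report %>% mutate(target = "sbp", .before = 1),
    x$regression$dbp$report %>% mutate(target = "dbp", .before = 1)
  )
}
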