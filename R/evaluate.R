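# Evaluation suite: MAE / absolute-error STD, British Hypertension
# Society grading, hypertension labelling, confusion-matrix metrics,
# ROC/AUC, and the 80/20 + 5-fold cross-validation harness.

#' Mean absolute error
#'
#' @param predicted,observed Numeric vectors of equal length (mmHg for BP).
#' @return Mean of `|predicted - observed|`.
#' @export
mae <- function(predicted, observed) {
  assert_that(length(predicted) == length(observed) && length(observed) >= 1,
              "need equal non-empty vectors")
  mean(abs(predicted - observed))
}

#' Standard deviation of absolute errors
#'
#' Sample standard deviation (divisor n-1) of `|predicted - observed|`,
#' the dispersion companion to [mae()].
#'
#' @param predicted,observed Numeric vectors of equal length, n >= 2.
#' @return SD of the absolute errors.
#' @export
abs_error_std <- function(predicted, observed) {
  assert_that(length(predicted) == length(observed) && length(observed) >= 2,
              "need equal vectors of length >= 2")
  sd(abs(predicted - observed))
}

# British Hypertension Society cumulative-percentage thresholds.
BHS_THRESHOLDS <- data.frame(
  grade = c("A", "B", "C"),
  p5 = c(60, 50, 40), p10 = c(85, 75, 65), p15 = c(95, 90, 85)
)

#' BHS grade from cumulative error percentages
#'
#' Grade A needs >= 60 / 85 / 95 % of absolute errors within 5 / 10 / 15
#' mmHg, B >= 50 / 75 / 90, C >= 40 / 65 / 85 (all three thresholds
#' required); anything worse is D.
#'
#' @param p5,p10,p15 Percentages of absolute errors within 5, 10, 15 mmHg.
#' @return `"A"`, `"B"`, `"C"` or `"D"`.
#' @export
bhs_letter <- function(p5, p10, p15) {
  for (i in seq_len(nrow(BHS_THRESHOLDS))) {
    t <- BHS_THRESHOLDS[i, ]
    if (p5 >= t$p5 && p10 >= t$p10 && p15 >= t$p15) return(t$grade)
  }
  "D"
}

#' BHS grading of a set of absolute errors
#'
#' @param abs_errors Absolute BP errors in mmHg (non-empty).
#' @return A tibble `(pct_within_5, pct_within_10, pct_within_15, grade)`.
#' @export
bhs_grade <- function(abs_errors) {
  assert_that(length(abs_errors) >= 1, "need at least one error")
  p5 <- 100 * mean(abs_errors <= 5)
  p10 <- 100 * mean(abs_errors <= 10)
  p15 <- 100 * mean(abs_errors <= 15)
  tibble(pct_within_5 = p5, pct_within_10 = p10, pct_within_15 = p15,
         grade = bhs_letter(p5, p10, p15))
}

#' Hypertension label from blood pressure
#'
#' Positive when SBP exceeds 130 mmHg or DBP exceeds 80 mmHg (strict
#' inequalities: the boundary values are negative).
#'
#' @param sbp,dbp Blood pressures in mmHg (vectorised).
#' @return Logical vector.
#' @export
label_hypertension <- function(sbp, dbp) {
  sbp > 130 | dbp > 80
}

#' Confusion counts for binary labels
#'
#' @param truth,predicted Logical (or coercible 2-level) vectors of equal
#'   length.
#' @return A list of class `confusion_counts`: `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(truth, predicted) {
  assert_that(length(truth) == length(predicted), "length mismatch")
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  assert_that(!anyNA(truth) && !anyNA(predicted),
              "labels must be binary (logical) without NA")
  structure(list(
    tp = sum(truth & predicted), fp = sum(!truth & predicted),
    fn = sum(truth & !predicted), tn = sum(!truth & !predicted)
  ), class = "confusion_counts")
}

#' Build confusion counts directly
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  assert_that(all(c(tp, fp, fn, tn) >= 0), "counts must be non-negative")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)` (= recall = TPR), specificity `TN/(FP+TN)`,
#' precision `TP/(TP+FP)`, and `F1 = 2PR/(P+R)`. Metrics with a zero
#' denominator are returned as `NA` rather than raising.
#'
#' @param counts A `confusion_counts` object.
#' @return A one-row tibble `(sensitivity, specificity, precision, recall,
#'   f1)`, all fractions in `[0, 1]` or `NA`.
#' @export
classification_metrics <- function(counts) {
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  with(counts, {
    sens <- safe_div(tp, tp + fn)
    spec <- safe_div(tn, fp + tn)
    prec <- safe_div(tp, tp + fp)
    f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
      2 * prec * sens / (prec + sens) else NA_real_
    tibble(sensitivity = sens, specificity = spec, precision = prec,
           recall = sens, f1 = f1)
  })
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (predicting
#' positive when `score >= threshold`), anchors the curve at (0,0) and
#' (1,1), and integrates by the trapezoidal rule — equivalent to the
#' pairwise probability `P(score+ > score-) + 0.5 P(tie)`.
#'
#' @param truth Logical labels (both classes present).
#' @param scores Numeric scores, higher = more positive.
#' @return A list of class `roc_result`: `curve` (tibble `fpr`, `tpr`,
#'   `threshold`) and `auc`.
#' @export
roc_auc <- function(truth, scores) {
  truth <- as.logical(truth)
  assert_that(any(truth) && any(!truth), "need both classes present")
  assert_that(length(truth) == length(scores), "length mismatch")
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  tpr <- vapply(thr, function(t) sum(truth & scores >= t) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(!truth & scores >= t) / n_neg,
                numeric(1))
  curve <- tibble(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                  threshold = c(Inf, thr, -Inf))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC =", round(x$auc, 4), "\n")
  invisible(x)
}

#' Seeded 80/20 split with 5-fold cross-validated averaging
#'
#' Splits the rows into a training and a held-out test portion, divides
#' the training portion into `folds` folds, trains one model per fold
#' (on the other `folds - 1` folds), and averages the five models'
#' predictions on the test portion.
#'
#' @param data Feature tibble.
#' @param y Numeric target aligned with `data`.
#' @param model_fun Function `(train_data, train_y) -> model` where the
#'   model supports `predict(model, newdata)`.
#' @param seed Seed for split and fold assignment.
#' @param test_frac Held-out fraction (default 0.2).
#' @param folds Number of CV folds (default 5).
#' @return A list of class `cv_result`: `test` (tibble `observed`,
#'   `predicted`), `fold_report` (per-fold validation MAE), `test_idx`,
#'   `fold_assignment`.
#' @export
cv_harness <- function(data, y, model_fun, seed = 1, test_frac = 0.2,
                       folds = 5) {
  n <- nrow(data)
  assert_that(n >= 10, "need at least 10 samples")
  set.seed(seed)
  test_idx <- sort(sample.int(n, round(test_frac * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  n_tr <- length(train_idx)
  assert_that(n_tr >= folds, "too few training samples for the fold count")
  fold_of <- sample(rep(seq_len(folds), length.out = n_tr))
  test_preds <- matrix(NA_real_, length(test_idx), folds)
  fold_mae <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- train_idx[fold_of != f]
    va <- train_idx[fold_of == f]
    m <- model_fun(data[tr, , drop = FALSE], y[tr])
    fold_mae[f] <- mae(predict(m, data[va, , drop = FALSE]), y[va])
    test_preds[, f] <- predict(m, data[test_idx, , drop = FALSE])
  }
  structure(list(
    test = tibble(observed = y[test_idx], predicted = rowMeans(test_preds)),
    fold_report = tibble(fold = seq_len(folds), val_mae = fold_mae,
                         n_val = as.integer(table(fold_of))),
    test_idx = test_idx,
    fold_assignment = tibble(row = train_idx, fold = fold_of)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", nrow(x$test), "test rows;",
      "test MAE =", round(mae(x$test$predicted, x$test$observed), 3), "\n")
  invisible(x)
}

#' Regression report for a prediction set
#'
#' @param predicted,observed Numeric vectors (mmHg).
#' @return A one-row tibble: `mae`, `std` (SD of absolute errors), BHS
#'   percentages and grade.
#' @export
regression_report <- function(predicted, observed) {
  e <- abs(predicted - observed)
  bind_cols(tibble(mae = mae(predicted, observed),
                   std = abs_error_std(predicted, observed)),
            bhs_grade(e))
}
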