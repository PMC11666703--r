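test_that("MAE and absolute-error STD match hand arithmetic and oracles", {
  expect_equal(mae(c(120, 130), c(125, 125)), 5)
  expect_equal(mae(1:5, 1:5), 0)
  expect_equal(abs_error_std(c(1, 3), c(1, 1)), sqrt(2))
  expect_equal(abs_error_std(c(5, 7, 9), c(3, 5, 7)), 0)
  set.seed(1)
  p <- rnorm(50, 120, 10); o <- rnorm(50, 120, 10)
  tot <- 0
  for (i in 1:50) tot <- tot + abs(p[i] - o[i])
  expect_equal(mae(p, o), tot / 50)
  e <- abs(p - o)
  expect_equal(abs_error_std(p, o), sqrt(sum((e - mean(e))^2) / 49))
  expect_error(mae(1:3, 1:4), "equal")
})

test_that("BHS grading is cumulative, monotone and correct at the corners", {
  g <- bhs_grade(rep(0, 10))
  expect_equal(c(g$pct_within_5, g$pct_within_10, g$pct_within_15),
               c(100, 100, 100))
  expect_equal(g$grade, "A")
  set.seed(2)
  r <- bhs_grade(abs(rnorm(100, 0, 8)))
  expect_lte(r$pct_within_5, r$pct_within_10)
  expect_lte(r$pct_within_10, r$pct_within_15)
  # grading is monotone: improving any percentage never worsens the grade
  ranks <- c(D = 0, C = 1, B = 2, A = 3)
  expect_gte(ranks[bhs_letter(60, 85, 95)], ranks[bhs_letter(50, 85, 95)])
  expect_gte(ranks[bhs_letter(55, 80, 95)], ranks[bhs_letter(55, 75, 95)])
  # all three thresholds are required
  expect_equal(bhs_letter(100, 100, 80), "D")
})

test_that("hypertension labelling uses strict clinical thresholds", {
  expect_true(label_hypertension(131, 70))
  expect_false(label_hypertension(130, 80))
  expect_true(label_hypertension(120, 81))
  expect_equal(label_hypertension(c(140, 100), c(60, 60)), c(TRUE, FALSE))
})

test_that("confusion counts tally correctly and flip symmetrically", {
  truth <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  pred <- c(TRUE, FALSE, FALSE, TRUE, TRUE)
  cc <- confusion(truth, pred)
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 5)
  expect_equal(cc$tp, 2); expect_equal(cc$fn, 1); expect_equal(cc$fp, 1)
  perfect <- confusion(truth, truth)
  expect_equal(perfect$fp, 0); expect_equal(perfect$fn, 0)
  flipped <- confusion(!truth, pred)
  expect_equal(flipped$tp, cc$fp); expect_equal(flipped$fn, cc$tn)
})

test_that("classification metrics are exact on perfect input and bounded", {
  m <- classification_metrics(confusion_counts(tp = 10, fp = 0, fn = 0,
                                               tn = 20))
  expect_equal(unlist(m), c(sensitivity = 1, specificity = 1, precision = 1,
                            recall = 1, f1 = 1))
  set.seed(3)
  for (i in 1:20) {
    cc <- confusion_counts(tp = sample(0:20, 1), fp = sample(1:20, 1),
                           fn = sample(1:20, 1), tn = sample(0:20, 1))
    mm <- classification_metrics(cc)
    if (!is.na(mm$f1)) {
      expect_gte(mm$f1, min(mm$precision, mm$recall) - 1e-12)
      expect_lte(mm$f1, max(mm$precision, mm$recall) + 1e-12)
    }
    expect_equal(mm$recall, mm$sensitivity)
  }
  # zero denominators flag NA instead of erroring
  z <- classification_metrics(confusion_counts(0, 0, 5, 10))
  expect_true(is.na(z$precision))
})

test_that("ROC/AUC equals the pairwise comparison oracle", {
  truth <- c(rep(TRUE, 4), rep(FALSE, 4))
  expect_equal(roc_auc(truth, c(4, 3.5, 3, 2.5, 2, 1, 0.5, 0))$auc, 1)
  expect_equal(roc_auc(truth, rep(1, 8))$auc, 0.5)
  set.seed(4)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    tr <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(tr) || all(tr)) next
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(roc_auc(tr, sc)$auc, pairwise_auc(tr, sc),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(TRUE, 5), rnorm(5)), "both classes")
})

test_that("ROC curves are anchored and monotone", {
  set.seed(5)
  r <- roc_auc(sample(c(TRUE, FALSE), 30, replace = TRUE), rnorm(30))
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
  expect_equal(utils::tail(r$curve$fpr, 1), 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("our AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  truth <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  scores <- rnorm(60) + truth
  ours <- roc_auc(truth, scores)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the CV harness partitions data correctly and averages models", {
  set.seed(7)
  d <- tibble::tibble(x = rnorm(100))
  y <- 2 * d$x + 1
  # deterministic model: identical across folds -> average equals single
  lm_factory <- function(data, yy) {
    structure(list(), class = "exact_model")
  }
  assign("predict.exact_model",
         function(object, newdata, ...) 2 * newdata$x + 1,
         envir = globalenv())
  on.exit(rm("predict.exact_model", envir = globalenv()), add = TRUE)
  cv <- cv_harness(d, y, lm_factory, seed = 1)
  expect_equal(cv$test$predicted, cv$test$observed, tolerance = 1e-12)
  # fold sizes differ by at most 1
  sizes <- table(cv$fold_assignment$fold)
  expect_lte(max(sizes) - min(sizes), 1)
  # each training sample sits in exactly 4 of 5 training folds
  expect_equal(nrow(cv$fold_assignment), 80)
  expect_equal(length(cv$test_idx), 20)
  expect_length(intersect(cv$test_idx, cv$fold_assignment$row), 0)
})

test_that("regression reports aggregate MAE, STD and BHS consistently", {
  set.seed(8)
  obs <- rnorm(80, 120, 15)
  pred <- obs + rnorm(80, 0, 5)
  rep <- regression_report(pred, obs)
  expect_equal(rep$mae, mae(pred, obs))
  expect_equal(rep$std, abs_error_std(pred, obs))
  expect_true(rep$grade %in% c("A", "B", "C", "D"))
})
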