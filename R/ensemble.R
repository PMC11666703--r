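# AdaBoost.R2 boosting regression with a pluggable base learner and
# weighted-median combination. The boosting loop, per-sample loss
# normalization, beta confidence weights and the weighted-median predictor
# are authored here; the base learners behind the contract are standard
# model fits (xgboost gradient-boosted trees, rpart trees, lm).

#' Base learner contract
#'
#' A base learner is a list with `fit(data, y, weights)` returning a
#' fitted object, `predict(fit, data)` returning numeric predictions, and
#' a `label`. Fitting with uniform weights must equal unweighted fitting.
#'
#' @param fit Function `(data, y, weights) -> fitted object`.
#' @param predict Function `(fitted, data) -> numeric`.
#' @param label Human-readable name.
#' @return A list of class `base_learner`.
#' @export
base_learner <- function(fit, predict, label = "custom") {
  structure(list(fit = fit, predict = predict, label = label),
            class = "base_learner")
}

#' Gradient-boosted-tree base learner
#'
#' Leaf-wise gradient-boosted regression trees (xgboost with
#' `grow_policy = "lossguide"`), parameterised to the pipeline's standard
#' configuration: 31 leaves, unlimited depth, learning rate 0.01, L1
#' regularization 0.1, minimum child weight 3, row subsample 0.9, column
#' subsample 0.7. `nrounds` defaults to 2000 trees; smaller values trade
#' accuracy for speed.
#'
#' @param nrounds Number of boosting trees per fit.
#' @param params Overrides merged over the defaults.
#' @param nthread Threads per fit (1 keeps results reproducible).
#' @return A `base_learner`.
#' @export
base_learner_gbm <- function(nrounds = 2000, params = list(), nthread = 1) {
  defaults <- list(
    max_leaves = 31, grow_policy = "lossguide", max_depth = 0,
    eta = 0.01, alpha = 0.1, min_child_weight = 3,
    subsample = 0.9, colsample_bytree = 0.7, seed = 6789,
    objective = "reg:squarederror", nthread = nthread
  )
  p <- utils::modifyList(defaults, params)
  base_learner(
    fit = function(data, y, weights) {
      d <- xgboost::xgb.DMatrix(as.matrix(data), label = y, weight = weights)
      xgboost::xgb.train(params = p, data = d, nrounds = nrounds, verbose = 0)
    },
    predict = function(fit, data) {
      predict(fit, xgboost::xgb.DMatrix(as.matrix(data)))
    },
    label = sprintf("gbm(%d trees)", nrounds)
  )
}

#' Regression-tree base learner (rpart)
#'
#' @param maxdepth Maximum tree depth (2 gives boosting-friendly stumps).
#' @param minbucket Minimum samples per leaf.
#' @return A `base_learner`.
#' @export
base_learner_tree <- function(maxdepth = 30, minbucket = 3) {
  base_learner(
    fit = function(data, y, weights) {
      df <- as.data.frame(data); df$.y <- y
      rpart::rpart(.y ~ ., data = df, weights = weights, method = "anova",
                   control = rpart::rpart.control(
                     maxdepth = maxdepth, minbucket = minbucket,
                     minsplit = 2 * minbucket, cp = 0, xval = 0,
                     maxsurrogate = 0, usesurrogate = 0))
    },
    predict = function(fit, data) {
      unname(predict(fit, as.data.frame(data)))
    },
    label = sprintf("tree(depth<=%d)", maxdepth)
  )
}

#' Linear-model base learner
#' @return A `base_learner`.
#' @export
base_learner_lm <- function() {
  base_learner(
    fit = function(data, y, weights) {
      df <- as.data.frame(data); df$.y <- y
      stats::lm(.y ~ ., data = df, weights = weights)
    },
    predict = function(fit, data) {
      unname(predict(fit, as.data.frame(data)))
    },
    label = "lm"
  )
}

#' Normalized per-sample boosting losses
#'
#' Absolute errors scaled by the maximum error so every loss lies in
#' `[0, 1]` with at least one loss equal to 1. `"linear"` is `e / max(e)`,
#' `"square"` its square, `"exponential"` is `1 - exp(-e / max(e))`.
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @param kind Loss family.
#' @return Numeric vector of losses in `[0, 1]`; all zero when the fit is
#'   perfect (caller handles that shortcut).
#' @export
normalized_losses <- function(predicted, observed,
                              kind = c("linear", "square", "exponential")) {
  kind <- match.arg(kind)
  assert_that(length(predicted) == length(observed), "length mismatch")
  e <- abs(predicted - observed)
  m <- max(e)
  if (m == 0) return(rep(0, length(e)))
  switch(kind,
         linear = e / m,
         square = (e / m)^2,
         exponential = 1 - exp(-e / m))
}

#' One AdaBoost.R2 weight update
#'
#' `D'[i] = D[i] * beta^(lr * (1 - L[i])) / Z` with `Z` the normalizer, so
#' low-loss samples (well predicted) are down-weighted by the confidence
#' factor `beta` and the distribution stays on the simplex.
#'
#' @param d Current weight distribution (sums to 1).
#' @param losses Normalized losses in `[0, 1]`.
#' @param beta Confidence parameter in (0, 1).
#' @param learning_rate Exponent scaling of the update.
#' @return Updated weight distribution.
#' @export
update_weights <- function(d, losses, beta, learning_rate = 1) {
  assert_that(beta > 0 && beta < 1, "beta must lie in (0, 1)")
  assert_that(all(losses >= 0 & losses <= 1), "losses must lie in [0, 1]")
  un <- d * beta^(learning_rate * (1 - losses))
  un / sum(un)
}

#' Fit an AdaBoost.R2 ensemble regressor
#'
#' Starts from uniform sample weights; each round draws a weighted
#' bootstrap resample (or passes weights through to the base learner),
#' fits a fresh base learner, computes normalized losses on the full
#' training set and their weighted average `Lbar = sum(D * L)`. Rounds
#' with `Lbar >= 0.5` are rejected and stop the loop; otherwise
#' `beta = Lbar / (1 - Lbar)` is stored and the weights are updated. A
#' perfect fit (all losses zero) is stored with near-total confidence and
#' also stops the loop.
#'
#' @param data Tibble/data frame of numeric features.
#' @param y Numeric target.
#' @param base A `base_learner` (default [base_learner_gbm()]).
#' @param rounds Maximum boosting rounds (default 300).
#' @param learning_rate Shrinkage on the weight update and prediction
#'   weights (default 0.1).
#' @param loss Loss family for [normalized_losses()].
#' @param resample If `TRUE` (default) fit on a weighted bootstrap
#'   resample; if `FALSE` pass the weights to the base learner directly.
#' @param seed Seed for the resampling stream.
#' @return An `adaboost_r2` model: fitted learners, `beta` per round, the
#'   feature registry snapshot, and a per-round training log tibble.
#' @examples
#' d <- tibble::tibble(x = runif(40))
#' m <- adaboost_r2(d, 2 * d$x + rnorm(40, 0, 0.05),
#'                  base = base_learner_tree(maxdepth = 2),
#'                  rounds = 5, seed = 1)
#' predict(m, d)[1:3]
#' @export
adaboost_r2 <- function(data, y, base = base_learner_gbm(),
                        rounds = 300, learning_rate = 0.1,
                        loss = c("linear", "square", "exponential"),
                        resample = TRUE, seed = 1) {
  loss <- match.arg(loss)
  assert_that(nrow(data) >= 10, "need at least 10 training samples")
  assert_that(all(vapply(data, function(v) all(is.finite(v)), logical(1))),
              "features must be finite")
  n <- nrow(data)
  set.seed(seed)
  d <- rep(1 / n, n)
  learners <- list()
  betas <- numeric(0)
  log <- list()
  for (t in seq_len(rounds)) {
    fit <- if (resample) {
      idx <- sample.int(n, n, replace = TRUE, prob = d)
      base$fit(data[idx, , drop = FALSE], y[idx], rep(1, n))
    } else {
      base$fit(data, y, d * n)
    }
    pred <- base$predict(fit, data)
    L <- normalized_losses(pred, y, loss)
    lbar <- sum(d * L)
    if (max(abs(pred - y)) == 0) {          # perfect fit shortcut
      learners[[length(learners) + 1]] <- fit
      betas <- c(betas, 1e-10)
      log[[length(log) + 1]] <- tibble(round = t, avg_loss = 0,
                                       beta = 1e-10, accepted = TRUE)
      break
    }
    if (lbar >= 0.5) {
      log[[length(log) + 1]] <- tibble(round = t, avg_loss = lbar,
                                       beta = NA_real_, accepted = FALSE)
      if (!length(learners)) {
        # degenerate first round: keep the learner so the model is usable
        learners[[1]] <- fit
        betas <- 0.5
        warn("first boosting round had average loss >= 0.5; kept as-is")
      }
      break
    }
    beta <- lbar / (1 - lbar)
    learners[[length(learners) + 1]] <- fit
    betas <- c(betas, beta)
    log[[length(log) + 1]] <- tibble(round = t, avg_loss = lbar,
                                     beta = beta, accepted = TRUE)
    d <- update_weights(d, L, beta, learning_rate)
  }
  assert_that(length(learners) >= 1, "boosting produced no learner")
  structure(list(
    learners = learners, betas = betas, base_label = base$label,
    base = base, learning_rate = learning_rate, loss = loss,
    features = names(data), log = bind_rows(log)
  ), class = "adaboost_r2")
}

#' Weighted median
#'
#' Sorts the values and returns the first whose cumulative weight reaches
#' half the total weight.
#'
#' @param x Numeric values.
#' @param w Non-negative weights.
#' @return The weighted median of `x`.
#' @export
weighted_median <- function(x, w) {
  ord <- order(x)
  cw <- cumsum(w[ord])
  x[ord][which(cw >= 0.5 * sum(w))[1]]
}

#' Predict from an AdaBoost.R2 model
#'
#' Per sample, the weighted median of the base learners' predictions with
#' weights `learning_rate * log(1 / beta_t)`.
#'
#' @param object An `adaboost_r2` model.
#' @param newdata Feature table with the training columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.adaboost_r2 <- function(object, newdata, ...) {
  newdata <- newdata[, object$features, drop = FALSE]
  preds <- vapply(object$learners,
                  function(f) object$base$predict(f, newdata),
                  numeric(nrow(newdata)))
  preds <- matrix(preds, nrow = nrow(newdata))
  w <- object$learning_rate * log(1 / object$betas)
  if (all(w == 0) || length(w) == 1) w <- rep(1, length(object$betas))
  apply(preds, 1, weighted_median, w = w)
}

#' @export
print.adaboost_r2 <- function(x, ...) {
  cat("<adaboost_r2> ", length(x$learners), " learners (base: ",
      x$base_label, "), loss = ", x$loss, "\n", sep = "")
  invisible(x)
}

#' @rdname adaboost_r2
#' @param x An `adaboost_r2` model.
#' @exportS3Method generics::tidy
tidy.adaboost_r2 <- function(x, ...) x$log

#' @rdname adaboost_r2
#' @exportS3Method generics::glance
glance.adaboost_r2 <- function(x, ...) {
  acc <- x$log[x$log$accepted, ]
  tibble(n_learners = length(x$learners),
         rounds_attempted = nrow(x$log),
         final_avg_loss = if (nrow(acc)) acc$avg_loss[nrow(acc)] else NA_real_,
         base = x$base_label, loss = x$loss,
         learning_rate = x$learning_rate)
}
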