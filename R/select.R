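# Feature ranking: Pearson correlation screening plus decision-tree
# impurity-decrease ("Gini") importance. The tree inducer is implemented
# here so every split's node statistics (N_t, G, child sizes and
# impurities) are recorded and the importance sum is fully auditable.

node_impurity <- function(y, task) {
  if (task == "classification") {
    p <- table(y) / length(y)
    1 - sum(p^2)
  } else {
    mean((y - mean(y))^2)           # variance, population form
  }
}

# Best split of y by numeric vector v: returns threshold and impurity
# pieces, or NULL when no admissible split improves.
best_split_feature <- function(v, y, task, min_leaf) {
  ord <- order(v)
  vs <- v[ord]; ys <- y[ord]
  n <- length(ys)
  ks <- which(vs[-n] < vs[-1])               # split after position k
  ks <- ks[ks >= min_leaf & (n - ks) >= min_leaf]
  if (!length(ks)) return(NULL)
  if (task == "classification") {
    pos <- cumsum(ys == levels(factor(y))[1])
    gl <- vapply(ks, function(k) {
      p <- pos[k] / k; 1 - p^2 - (1 - p)^2
    }, numeric(1))
    gr <- vapply(ks, function(k) {
      p <- (pos[n] - pos[k]) / (n - k); 1 - p^2 - (1 - p)^2
    }, numeric(1))
  } else {
    cs <- cumsum(ys); cs2 <- cumsum(ys^2)
    gl <- cs2[ks] / ks - (cs[ks] / ks)^2
    gr <- (cs2[n] - cs2[ks]) / (n - ks) - ((cs[n] - cs[ks]) / (n - ks))^2
  }
  w <- ks / n * gl + (n - ks) / n * gr
  b <- which.min(w)
  k <- ks[b]
  list(threshold = (vs[k] + vs[k + 1]) / 2, n_left = k, n_right = n - k,
       g_left = max(gl[b], 0), g_right = max(gr[b], 0))
}

#' Fit a CART decision tree
#'
#' Greedy binary recursive partitioning over numeric features, with Gini
#' impurity for classification and variance for regression. Splits are
#' searched exhaustively; ties between features resolve to the earlier
#' column, so fits are deterministic for a fixed column order.
#'
#' @param data Data frame / tibble of numeric feature columns.
#' @param y Target vector (numeric, or 2-level factor/logical for
#'   classification).
#' @param task `"regression"` or `"classification"`.
#' @param min_leaf Minimum samples per leaf (default 3).
#' @param max_depth Maximum depth.
#' @return A list of class `cart_tree` with the recursive `root` node and
#'   metadata; each internal node records `feature`, `threshold`, `n`,
#'   `impurity`, child impurities/sizes and its weighted impurity
#'   decrease `delta`.
#' @export
fit_cart <- function(data, y, task = c("regression", "classification"),
                     min_leaf = 3, max_depth = 30) {
  task <- match.arg(task)
  data <- as.data.frame(data)
  assert_that(all(vapply(data, is.numeric, logical(1))),
              "all features must be numeric")
  if (task == "classification") {
    y <- factor(y)
    assert_that(nlevels(y) == 2, "classification trees support binary targets")
  }
  N <- nrow(data)
  build <- function(idx, depth) {
    yy <- y[idx]
    G <- node_impurity(yy, task)
    node <- list(n = length(idx), impurity = G,
                 value = if (task == "regression") mean(yy) else
                   names(which.max(table(yy))))
    if (G <= 1e-12 || length(idx) < 2 * min_leaf || depth >= max_depth) {
      node$is_leaf <- TRUE
      return(node)
    }
    best <- NULL
    for (j in seq_along(data)) {
      sp <- best_split_feature(data[[j]][idx], yy, task, min_leaf)
      if (is.null(sp)) next
      nt <- length(idx)
      delta <- (nt / N) *
        (G - sp$n_right / nt * sp$g_right - sp$n_left / nt * sp$g_left)
      if (is.null(best) || delta > best$delta + 1e-15) {
        best <- c(sp, list(feature = names(data)[j], delta = delta))
      }
    }
    if (is.null(best) || best$delta <= 1e-12) {
      node$is_leaf <- TRUE
      return(node)
    }
    left_idx <- idx[data[[best$feature]][idx] <= best$threshold]
    right_idx <- setdiff(idx, left_idx)
    node$is_leaf <- FALSE
    node$feature <- best$feature
    node$threshold <- best$threshold
    node$g_left <- best$g_left; node$g_right <- best$g_right
    node$n_left <- best$n_left; node$n_right <- best$n_right
    node$delta <- best$delta
    node$left <- build(left_idx, depth + 1)
    node$right <- build(right_idx, depth + 1)
    node
  }
  structure(list(root = build(seq_len(N), 0), n = N, task = task,
                 features = names(data)),
            class = "cart_tree")
}

#' @export
predict.cart_tree <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  walk <- function(node, i) {
    while (!node$is_leaf) {
      node <- if (newdata[[node$feature]][i] <= node$threshold)
        node$left else node$right
    }
    node$value
  }
  out <- vapply(seq_len(nrow(newdata)), function(i) walk(object$root, i),
                if (object$task == "regression") numeric(1) else character(1))
  if (object$task == "regression") out else out
}

# Collect every internal node of a cart_tree into a flat list.
tree_nodes <- function(tree) {
  acc <- list()
  rec <- function(node) {
    if (node$is_leaf) return(invisible(NULL))
    acc[[length(acc) + 1]] <<- node
    rec(node$left); rec(node$right)
  }
  rec(tree$root)
  acc
}

#' Decision-tree Gini importance
#'
#' Importance of a feature is the sum, over every internal node splitting
#' on it, of the weighted impurity decrease
#' `(N_t / N) * (G - N_tR/N_t * G_R - N_tL/N_t * G_L)`,
#' normalized so all importances sum to 1 (Gini impurity for
#' classification, variance for regression).
#'
#' @param data Tibble of feature columns plus the target.
#' @param target Name of the target column.
#' @param task `"regression"` or `"classification"`.
#' @param min_leaf,max_depth Tree controls (see [fit_cart()]).
#' @param seed Optional seed (fits are deterministic; kept for interface
#'   symmetry with stochastic rankers).
#' @return A tibble `(feature, importance)` sorted by decreasing
#'   importance, with the fitted tree in `attr(, "tree")`.
#' @export
gini_importance <- function(data, target,
                            task = c("regression", "classification"),
                            min_leaf = 3, max_depth = 30, seed = NULL) {
  task <- match.arg(task)
  assert_that(target %in% names(data), paste("no column", target))
  if (!is.null(seed)) set.seed(seed)
  y <- data[[target]]
  x <- data[setdiff(names(data), target)]
  x <- x[vapply(x, is.numeric, logical(1))]
  tree <- fit_cart(x, y, task, min_leaf, max_depth)
  imp <- setNames(numeric(length(x)), names(x))
  for (node in tree_nodes(tree)) {
    imp[node$feature] <- imp[node$feature] + node$delta
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  out <- tibble(feature = names(imp), importance = unname(imp)) %>%
    arrange(dplyr::desc(.data$importance))
  attr(out, "tree") <- tree
  out
}

#' Pairwise Pearson correlation matrix of a feature table
#'
#' @param data Tibble; non-numeric columns are dropped. Constant columns
#'   yield `NA` correlations and a warning.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(data) {
  x <- as.data.frame(data)
  x <- x[vapply(x, is.numeric, logical(1))]
  assert_that(nrow(x) >= 2, "need at least 2 rows")
  const <- vapply(x, function(v) var(v, na.rm = TRUE) == 0, logical(1))
  if (any(const)) {
    warn(paste("constant columns have undefined correlations:",
               paste(names(x)[const], collapse = ", ")))
  }
  m <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  diag(m) <- 1
  m
}

#' Correlation-screened feature selection
#'
#' For every pair of features with `|r|` above `cor_threshold`, drops the
#' lower-importance member; then keeps features with non-zero importance,
#' ordered by decreasing importance.
#'
#' @param importances Tibble from [gini_importance()].
#' @param correlations Matrix from [correlation_matrix()] over the same
#'   features.
#' @param cor_threshold Absolute-correlation drop threshold (default 0.9).
#' @return Character vector of selected feature names.
#' @export
select_features <- function(importances, correlations, cor_threshold = 0.9) {
  imp <- setNames(importances$importance, importances$feature)
  feats <- intersect(names(imp), rownames(correlations))
  cm <- correlations[feats, feats, drop = FALSE]
  pairs <- which(abs(cm) > cor_threshold & upper.tri(cm), arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(-abs(cm[pairs]))
    dropped <- character(0)
    for (r in ord) {
      a <- feats[pairs[r, 1]]; b <- feats[pairs[r, 2]]
      if (a %in% dropped || b %in% dropped) next
      dropped <- c(dropped, if (imp[a] >= imp[b]) b else a)
    }
    feats <- setdiff(feats, dropped)
  }
  feats <- feats[imp[feats] > 0]
  assert_that(length(feats) > 0, "no features survive selection")
  feats[order(-imp[feats])]
}

#' Preset feature subsets
#'
#' The curated subsets used by the regression and classification stages:
#' for SBP/DBP, physical features excluding gender plus DW25/DW75, LASI,
#' the cA4/cD3/cD2 statistics and the systolic/diastolic periods; for
#' hypertension classification, BMI/age/gender/weight plus s1/s3/s4,
#' DW25/DW50, LASI, the cA4/cD4/cD2 statistics, the diastolic peak value
#' and the period.
#'
#' @param which One of `"sbp"`, `"dbp"`, `"htn"`.
#' @return Character vector of feature names (subset of
#'   [feature_registry()]).
#' @export
feature_preset <- function(which = c("sbp", "dbp", "htn")) {
  which <- match.arg(which)
  wav <- function(b) paste0(b, c("_max", "_min", "_mean", "_std"))
  if (which %in% c("sbp", "dbp")) {
    c("age", "height", "weight", "bmi",
      "DW25", "DW75", "LASI",
      wav("cA4"), wav("cD3"), wav("cD2"),
      "sys_period", "dia_period")
  } else {
    c("bmi", "age", "gender", "weight",
      "s1", "s3", "s4", "DW25", "DW50", "LASI",
      wav("cA4"), wav("cD4"), wav("cD2"),
      "dia_peak_value", "period")
  }
}
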