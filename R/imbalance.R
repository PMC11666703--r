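# Class-imbalance handling for the hypertension task: random majority
# undersampling and SMOTE (synthetic minority over-sampling by
# nearest-neighbour interpolation).

#' Euclidean distance between two points
#'
#' @param p,q Numeric vectors of equal length.
#' @return `sqrt(sum((p - q)^2))`.
#' @export
euclidean <- function(p, q) {
  assert_that(length(p) == length(q), "dimension mismatch")
  sqrt(sum((p - q)^2))
}

check_binary <- function(labels) {
  lv <- unique(labels)
  assert_that(length(lv) == 2,
              "need exactly two classes (both non-empty)")
  n1 <- sum(labels == lv[1])
  n2 <- length(labels) - n1
  if (n1 <= n2) {
    list(minority = lv[1], majority = lv[2], n_min = n1, n_maj = n2)
  } else {
    list(minority = lv[2], majority = lv[1], n_min = n2, n_maj = n1)
  }
}

#' Random majority-class undersampling
#'
#' Randomly removes majority-class rows (without replacement) until both
#' classes have the minority count; minority rows are untouched.
#'
#' @param data Feature tibble.
#' @param labels Binary label vector aligned with `data` rows.
#' @param seed Seed for the removal draw.
#' @return A list `(data, labels)` with balanced classes; rows are a
#'   subset of the input.
#' @export
undersample <- function(data, labels, seed = 1) {
  info <- check_binary(labels)
  set.seed(seed)
  maj_idx <- which(labels == info$majority)
  keep_maj <- sort(sample(maj_idx, info$n_min))
  keep <- sort(c(which(labels == info$minority), keep_maj))
  list(data = data[keep, , drop = FALSE], labels = labels[keep])
}

#' SMOTE minority oversampling
#'
#' For each minority sample `x`, the `k` nearest minority neighbours by
#' Euclidean distance are found (ties broken by row order); synthetic
#' samples `x_new = x + rand(0,1) * (x_n - x)` are generated — cycling
#' over the minority points, each time picking one of the `k` neighbours
#' uniformly and a fresh uniform gap — until the classes are exactly
#' balanced. Original rows are retained unchanged.
#'
#' @param data Numeric feature tibble.
#' @param labels Binary label vector.
#' @param k Number of nearest neighbours (default 3; must be smaller than
#'   the minority count).
#' @param seed Seed for neighbour and gap draws.
#' @return A list `(data, labels, synthetic)` where `synthetic` is a
#'   logical marker (FALSE for every original row) and classes balance
#'   exactly.
#' @export
smote <- function(data, labels, k = 3, seed = 1) {
  info <- check_binary(labels)
  assert_that(info$n_min > k,
              sprintf("minority count (%d) must exceed k (%d)",
                      info$n_min, k))
  set.seed(seed)
  x <- as.matrix(data[, vapply(data, is.numeric, logical(1)), drop = FALSE])
  min_idx <- which(labels == info$minority)
  xm <- x[min_idx, , drop = FALSE]
  dm <- as.matrix(stats::dist(xm))
  # k nearest minority neighbours, self excluded, stable order on ties
  nn <- t(apply(dm, 1, function(row) {
    order(row, seq_along(row))[2:(k + 1)]
  }))
  n_new <- info$n_maj - info$n_min
  synth <- matrix(NA_real_, n_new, ncol(xm),
                  dimnames = list(NULL, colnames(xm)))
  for (s in seq_len(n_new)) {
    i <- ((s - 1) %% info$n_min) + 1
    j <- nn[i, sample.int(k, 1)]
    gap <- runif(1)
    synth[s, ] <- xm[i, ] + gap * (xm[j, ] - xm[i, ])
  }
  out_x <- bind_rows(as_tibble(as.data.frame(x)),
                     as_tibble(as.data.frame(synth)))
  list(
    data = out_x,
    labels = c(labels, rep(info$minority, n_new)),
    synthetic = c(rep(FALSE, length(labels)), rep(TRUE, n_new))
  )
}

#' Rebalance a labelled dataset
#'
#' Dispatcher over the supported strategies.
#'
#' @param data Feature tibble.
#' @param labels Binary labels.
#' @param method `"none"`, `"undersample"` or `"smote"`.
#' @param k SMOTE neighbour count.
#' @param seed Seed.
#' @return A list `(data, labels)` (plus `synthetic` for SMOTE).
#' @export
rebalance <- function(data, labels,
                      method = c("none", "undersample", "smote"),
                      k = 3, seed = 1) {
  method <- match.arg(method)
  switch(method,
         none = list(data = data, labels = labels),
         undersample = undersample(data, labels, seed),
         smote = smote(data, labels, k, seed))
}
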