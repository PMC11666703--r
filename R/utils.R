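`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Draw from a truncated normal by rejection
#'
#' Vectorised rejection sampler; the bounds used here are always several
#' standard deviations wide, so rejection is cheap.
#' @noRd
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "ppgbp_error")
  invisible(TRUE)
}

#' Fisher-Pearson coefficient of skewness
#'
#' The population form: `g = sum((x - mean(x))^3) / (n * s^3)` with `s`
#' the population standard deviation (divisor `n`). Used both as the
#' `fisher` waveform feature and as the segment-level S-SQI quality score.
#'
#' @param x Numeric vector, at least 3 values, not all equal.
#' @return A single numeric skewness value.
#' @examples
#' fisher_skewness(c(1, 1, 1, 7))
#' @export
fisher_skewness <- function(x) {
  assert_that(is.numeric(x) && length(x) >= 3, "need at least 3 numeric values")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  assert_that(s > 0, "skewness undefined for a constant input")
  sum((x - m)^3) / (length(x) * s^3)
}
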