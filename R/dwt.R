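# Periodized orthogonal discrete wavelet transform (Mallat pyramid).
# Implemented in-package: the decomposition filters are the standard
# Daubechies constants, the extension mode is circular so the transform is
# exactly orthogonal (energy-preserving) at every level.

WAVELET_FILTERS <- list(
  haar = list(
    lo = c(0.7071067811865476, 0.7071067811865476),
    hi = c(0.7071067811865476, -0.7071067811865476)
  ),
  db4 = list(
    lo = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
           -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
           0.7148465705529157, 0.2303778133088965),
    hi = c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
           -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
           -0.0328830116668852, -0.010597401785069032)
  )
)

# One analysis level: circular correlation with each filter, downsample by 2.
dwt_step <- function(x, filt) {
  n <- length(x)
  L <- length(filt$lo)
  idx <- outer(2 * (seq_len(n / 2) - 1), seq_len(L) - 1, "+") %% n + 1
  xm <- matrix(x[idx], nrow = n / 2)
  list(cA = as.numeric(xm %*% filt$lo),
       cD = as.numeric(xm %*% filt$hi))
}

#' Multilevel discrete wavelet decomposition
#'
#' Periodized orthogonal DWT. The input length must be divisible by
#' `2^levels` and each level's input must be at least as long as the
#' filter (8 taps for `db4`), so 4-level `db4` needs at least 128 samples.
#'
#' @param x Numeric vector.
#' @param levels Decomposition depth (default 4).
#' @param wavelet `"db4"` (default) or `"haar"`.
#' @return A list with approximation `cA<levels>` and details `cD1` (finest)
#'   through `cD<levels>`.
#' @examples
#' d <- dwt_multilevel(sin(2 * pi * (0:127) / 32))
#' names(d)
#' @export
dwt_multilevel <- function(x, levels = 4, wavelet = c("db4", "haar")) {
  wavelet <- match.arg(wavelet)
  filt <- WAVELET_FILTERS[[wavelet]]
  L <- length(filt$lo)
  n <- length(x)
  assert_that(n %% 2^levels == 0,
              sprintf("input length %d is not divisible by 2^%d", n, levels))
  assert_that(n / 2^(levels - 1) >= L,
              sprintf("input too short: %d-level %s needs at least %d samples",
                      levels, wavelet, L * 2^(levels - 1)))
  out <- list()
  cur <- x
  for (lev in seq_len(levels)) {
    st <- dwt_step(cur, filt)
    out[[paste0("cD", lev)]] <- st$cD
    cur <- st$cA
  }
  out[[paste0("cA", levels)]] <- cur
  out[c(paste0("cA", levels), paste0("cD", seq_len(levels)))]
}
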