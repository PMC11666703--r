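# Preprocessing: spectrum inspection, zero-phase Butterworth band-pass,
# min-max normalization, skewness quality gating, single-cycle segmentation.

#' Construct a PPG segment
#'
#' A `ppg_segment` is a tibble with columns `time_s` and `amplitude` and
#' attributes `sampling_rate`, `subject_id`, optional `sqi` and optional
#' generator ground `truth`.
#'
#' @param amplitude Numeric sample vector (at least 2 samples).
#' @param sampling_rate Sampling rate in Hz.
#' @param subject_id Optional subject identifier.
#' @param sqi Optional precomputed quality score.
#' @param truth Optional generator ground-truth list.
#' @return A `ppg_segment` tibble.
#' @export
new_ppg_segment <- function(amplitude, sampling_rate,
                            subject_id = NA_character_, sqi = NULL,
                            truth = NULL) {
  assert_that(length(amplitude) >= 2, "a segment needs at least 2 samples")
  assert_that(sampling_rate > 0, "sampling_rate must be positive")
  out <- tibble(time_s = (seq_along(amplitude) - 1) / sampling_rate,
                amplitude = as.numeric(amplitude))
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "subject_id") <- subject_id
  if (!is.null(sqi)) attr(out, "sqi") <- sqi
  if (!is.null(truth)) attr(out, "truth") <- truth
  class(out) <- c("ppg_segment", class(out))
  out
}

seg_fs <- function(seg) attr(seg, "sampling_rate")

# Rebuild a segment with new samples, keeping metadata.
seg_update <- function(seg, amplitude, sqi = attr(seg, "sqi")) {
  new_ppg_segment(amplitude, seg_fs(seg),
                  subject_id = attr(seg, "subject_id"), sqi = sqi,
                  truth = attr(seg, "truth"))
}

#' One-sided magnitude spectrum of a segment
#'
#' FFT-based inspection used to pick the band-pass corner frequencies: for
#' a clean PPG segment the dominant non-DC peak sits at the heart-rate
#' frequency (~1-1.5 Hz) with harmonics near 3 and 4.5 Hz.
#'
#' @param seg A `ppg_segment`.
#' @return A tibble `(frequency_hz, magnitude)` covering 0..fs/2.
#' @export
compute_spectrum <- function(seg) {
  x <- seg$amplitude
  assert_that(length(x) >= 2, "need at least 2 samples")
  n <- length(x)
  mag <- Mod(fft(x)) / n
  n_keep <- floor(n / 2) + 1L
  tibble(
    frequency_hz = (seq_len(n_keep) - 1) * seg_fs(seg) / n,
    magnitude = mag[seq_len(n_keep)]
  )
}

#' Band-pass filter specification
#'
#' Sixth-order Butterworth band-pass over 0.5-5 Hz by default, the band
#' that retains the cardiac fundamental and its first few harmonics while
#' rejecting baseline wander and high-frequency noise.
#'
#' @param low_cut,high_cut Corner frequencies in Hz.
#' @param order Total filter order (must be even; 6 by default).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 0.5, high_cut = 5, order = 6) {
  assert_that(low_cut > 0 && high_cut > low_cut, "need 0 < low_cut < high_cut")
  assert_that(order %% 2 == 0 && order >= 2, "order must be a positive even number")
  structure(list(low_cut = low_cut, high_cut = high_cut, order = order,
                 family = "Butterworth band-pass"),
            class = "filter_spec")
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies the band-pass forward and backward (`signal::filtfilt`) so the
#' fiducial timings are not lag-shifted. `spec$order` is the order of the
#' band-pass; `signal::butter` is called with `order/2` sections.
#'
#' @param seg A `ppg_segment`.
#' @param spec A [filter_spec()].
#' @return The filtered `ppg_segment` (same length).
#' @export
bandpass <- function(seg, spec = filter_spec()) {
  fs <- seg_fs(seg)
  assert_that(spec$high_cut < fs / 2,
              "high_cut must be below the Nyquist frequency")
  b <- signal::butter(spec$order / 2,
                      c(spec$low_cut, spec$high_cut) / (fs / 2),
                      type = "pass")
  seg_update(seg, signal::filtfilt(b, seg$amplitude))
}

#' Min-max normalize a segment to [0, 1]
#'
#' @param seg A `ppg_segment` with non-constant samples.
#' @return The normalized `ppg_segment` (min exactly 0, max exactly 1).
#' @export
normalize_segment <- function(seg) {
  x <- seg$amplitude
  r <- range(x)
  assert_that(r[2] > r[1], "cannot normalize a constant segment")
  seg_update(seg, (x - r[1]) / (r[2] - r[1]))
}

#' Skewness signal quality index (S-SQI)
#'
#' The Fisher-Pearson skewness of the segment's amplitude distribution.
#' Clean PPG pulses are right-skewed (narrow systolic peaks over a broad
#' baseline), so higher values indicate better quality; symmetric noise
#' drives the score toward 0.
#'
#' @param seg A `ppg_segment` (>= 3 samples, non-constant).
#' @return A single numeric quality score.
#' @export
ssqi <- function(seg) fisher_skewness(seg$amplitude)

#' Quality gate over a table of segments
#'
#' Keeps segments whose S-SQI is at least `threshold` and which contain at
#' least one complete detected pulse cycle; everything else is logged to
#' the rejection attribute.
#'
#' @param segments Tibble with a `segment` list-column of `ppg_segment`s
#'   (already filtered + normalized).
#' @param threshold Minimum S-SQI (no universal default exists; 0 keeps all
#'   right-skewed, i.e. pulse-like, segments).
#' @return The kept rows, with `sqi` and `n_cycles` columns added and an
#'   attribute `rejection_log` (tibble of counts by reason).
#' @export
quality_filter <- function(segments, threshold = 0) {
  scored <- segments %>%
    mutate(
      sqi = purrr::map_dbl(.data$segment, ssqi),
      n_cycles = purrr::map_int(.data$segment, ~ nrow(segment_cycles(.x)))
    )
  keep <- scored$sqi >= threshold & scored$n_cycles >= 1L
  log <- tibble(
    reason = c("kept", "low_sqi", "no_complete_cycle"),
    n = c(sum(keep),
          sum(scored$sqi < threshold),
          sum(scored$sqi >= threshold & scored$n_cycles < 1L))
  )
  out <- scored[keep, , drop = FALSE]
  attr(out, "rejection_log") <- log
  out
}

# Local maxima indices of x (strict left, non-strict right).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Topographic prominence of each candidate peak.
peak_prominence <- function(x, idx) {
  vapply(idx, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1)]
    higher_l <- which(left > h)
    lmin <- min(x[(if (length(higher_l)) max(higher_l) else 1L):i])
    right <- x[i:length(x)]
    higher_r <- which(right > h)
    rmin <- min(x[i:(if (length(higher_r)) i + min(higher_r) - 1L
                     else length(x))])
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect systolic peaks in a segment
#'
#' Prominence-gated local maxima with a minimum inter-peak distance
#' (defaults: prominence >= 0.2 of the amplitude range, distance >= 0.4 s,
#' i.e. a 150 bpm ceiling).
#'
#' @param seg A `ppg_segment`.
#' @param min_distance_s Minimum peak separation in seconds.
#' @param min_prominence_frac Minimum prominence as a fraction of the
#'   amplitude range.
#' @return Integer sample indices of retained peaks (sorted).
#' @export
find_systolic_peaks <- function(seg, min_distance_s = 0.4,
                                min_prominence_frac = 0.2) {
  x <- seg$amplitude
  rng <- diff(range(x))
  if (rng == 0) return(integer(0))
  cand <- local_maxima(x)
  if (!length(cand)) return(integer(0))
  prom <- peak_prominence(x, cand)
  cand <- cand[prom >= min_prominence_frac * rng]
  if (!length(cand)) return(integer(0))
  min_gap <- round(min_distance_s * seg_fs(seg))
  keep <- integer(0)
  for (i in cand[order(-x[cand])]) {     # greedy by height
    if (!length(keep) || all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Split a segment into complete foot-to-foot pulse cycles
#'
#' Feet are the minima between successive systolic peaks; the stretch
#' before the first peak also contributes its minimum (it is the true foot
#' whether the segment starts at onset or mid-fall). The cycle of the last
#' detected peak has no closing foot inside the segment — the next beat's
#' rise is missing — so it is dropped as incomplete, as are leading
#' partial beats.
#'
#' @param seg A filtered, normalized `ppg_segment`.
#' @param min_distance_s,min_prominence_frac Passed to
#'   [find_systolic_peaks()].
#' @return A tibble with one row per complete cycle: `cycle_id`,
#'   `foot_idx`, `end_idx` (sample indices into `seg`), and a `cycle`
#'   list-column of `ppg_cycle` objects. Zero rows if no peaks are found.
#' @export
segment_cycles <- function(seg, min_distance_s = 0.4,
                           min_prominence_frac = 0.2) {
  x <- seg$amplitude
  n <- length(x)
  empty <- tibble(cycle_id = integer(0), foot_idx = integer(0),
                  end_idx = integer(0), cycle = list())
  peaks <- find_systolic_peaks(seg, min_distance_s, min_prominence_frac)
  if (length(peaks) < 1) return(empty)
  feet <- integer(0)
  pre <- seq_len(peaks[1])
  feet <- c(feet, pre[which.min(x[pre])])
  if (length(peaks) >= 2) {
    for (j in seq_len(length(peaks) - 1)) {
      span <- peaks[j]:peaks[j + 1]
      feet <- c(feet, span[which.min(x[span])])
    }
  }
  feet <- sort(unique(feet))
  if (length(feet) < 2) return(empty)
  rows <- purrr::map(seq_len(length(feet) - 1), function(j) {
    i0 <- feet[j]; i1 <- feet[j + 1]
    # a complete cycle must contain exactly one retained systolic peak
    if (sum(peaks > i0 & peaks < i1) != 1) return(NULL)
    tibble(cycle_id = j, foot_idx = i0, end_idx = i1,
           cycle = list(new_ppg_cycle(x[i0:i1], seg_fs(seg))))
  })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out)) out$cycle_id <- seq_len(nrow(out))
  if (!nrow(out)) empty else out
}

#' Construct a single pulse cycle
#'
#' @param amplitude Foot-to-foot samples of one beat (>= 8 samples).
#' @param sampling_rate Sampling rate in Hz.
#' @return A `ppg_cycle` tibble `(time_s, amplitude)`.
#' @export
new_ppg_cycle <- function(amplitude, sampling_rate) {
  assert_that(length(amplitude) >= 8, "a cycle needs at least 8 samples")
  out <- tibble(time_s = (seq_along(amplitude) - 1) / sampling_rate,
                amplitude = as.numeric(amplitude))
  attr(out, "sampling_rate") <- sampling_rate
  class(out) <- c("ppg_cycle", class(out))
  out
}

#' Preprocess a table of raw segments
#'
#' The standard chain: band-pass -> min-max normalize -> S-SQI gate.
#'
#' @param segments Tibble with a `segment` list-column of raw
#'   `ppg_segment`s.
#' @param spec A [filter_spec()].
#' @param sqi_threshold Passed to [quality_filter()].
#' @return The surviving rows with filtered, normalized segments and
#'   `sqi`/`n_cycles` columns; rejection log in `attr(, "rejection_log")`.
#' @export
preprocess_segments <- function(segments, spec = filter_spec(),
                                sqi_threshold = 0) {
  cleaned <- segments %>%
    mutate(segment = purrr::map(.data$segment,
                                ~ normalize_segment(bandpass(.x, spec))))
  quality_filter(cleaned, sqi_threshold)
}
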