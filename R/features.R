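# Pulse wave analysis: fiducial-point detection and the morphological
# feature extractor (time-domain, width, amplitude, area and wavelet
# features, plus subject demographics).

#' Detect fiducial points on one pulse cycle
#'
#' Landmarks on a foot-to-foot beat: the foot (index 1 by construction),
#' the maximum-slope point on the rising limb (argmax of the first
#' difference before the systolic peak), the systolic peak (global
#' maximum, required within the first 60% of the cycle), and the diastolic
#' peak (most prominent local maximum after the systolic peak; if the
#' reflected wave is only a shoulder, the inflection point — minimum
#' absolute second difference after the peak — is used and flagged).
#'
#' @param cycle A `ppg_cycle`.
#' @return A list of class `fiducial_set`: `foot_idx`, `max_slope_idx`,
#'   `max_slope_value` (amplitude units per second), `sys_peak_idx`,
#'   `sys_peak_value`, `dia_peak_idx`, `dia_peak_value`,
#'   `dia_peak_inflection` (logical flag), `n`, `sampling_rate`.
#' @export
detect_fiducials <- function(cycle) {
  x <- cycle$amplitude
  n <- length(x)
  fs <- attr(cycle, "sampling_rate")
  sys_idx <- which.max(x)
  assert_that(sys_idx <= ceiling(0.6 * n),
              "malformed cycle: no systolic peak in the first 60%")
  assert_that(sys_idx > 1, "malformed cycle: peak at the foot")
  d1 <- diff(x)
  ms_idx <- which.max(d1[seq_len(sys_idx - 1)])
  after <- if (sys_idx + 1 <= n) (sys_idx + 1):n else integer(0)
  lm <- local_maxima(x)
  lm <- lm[lm > sys_idx]
  inflection <- FALSE
  if (length(lm)) {
    prom <- peak_prominence(x, lm)
    dia_idx <- lm[which.max(prom)]
  } else {
    # shoulder case: flattest curvature after the peak, away from the ends
    d2 <- diff(x, differences = 2)          # d2[i] ~ curvature at i+1
    cand <- after[after > sys_idx + 1 & after < n - 1]
    if (!length(cand)) cand <- after[after < n]
    dia_idx <- cand[which.min(abs(d2[cand - 1]))]
    inflection <- TRUE
  }
  structure(list(
    foot_idx = 1L,
    max_slope_idx = as.integer(ms_idx),
    max_slope_value = max(d1[seq_len(sys_idx - 1)]) * fs,
    sys_peak_idx = as.integer(sys_idx),
    sys_peak_value = x[sys_idx],
    dia_peak_idx = as.integer(dia_idx),
    dia_peak_value = x[dia_idx],
    dia_peak_inflection = inflection,
    n = n, sampling_rate = fs
  ), class = "fiducial_set")
}

#' Basic per-cycle statistics
#'
#' Period, moments and fiducial timings. Index-type features are reported
#' in seconds from the foot so they are sampling-rate invariant.
#'
#' @param cycle A `ppg_cycle`.
#' @param fid Its [detect_fiducials()] result.
#' @return A named numeric vector: `period`, `mean`, `STD`, `RMS`,
#'   `max_slope_idx` (s), `max_slope_value`, `sys_period` (s),
#'   `dia_period` (s), `dia_peak_idx` (s), `dia_peak_value`, `fisher`.
#' @export
basic_stats <- function(cycle, fid) {
  x <- cycle$amplitude
  fs <- fid$sampling_rate
  n <- length(x)
  c(period = n / fs,
    mean = mean(x),
    STD = sd(x),
    RMS = sqrt(mean(x^2)),
    max_slope_idx = (fid$max_slope_idx - fid$foot_idx) / fs,
    max_slope_value = fid$max_slope_value,
    sys_period = (fid$sys_peak_idx - fid$foot_idx) / fs,
    dia_period = (n - fid$sys_peak_idx) / fs,
    dia_peak_idx = (fid$dia_peak_idx - fid$foot_idx) / fs,
    dia_peak_value = fid$dia_peak_value,
    fisher = fisher_skewness(x))
}

# Sub-sample crossing time (in samples from cycle start, 0-based) of level
# `lev` between indices i and i+1, by linear interpolation.
cross_time <- function(x, i, lev) {
  (i - 1) + (lev - x[i]) / (x[i + 1] - x[i])
}

#' Fractional pulse widths (systolic and diastolic side)
#'
#' At `fraction` of the pulse height (systolic peak amplitude minus foot
#' amplitude above the foot): SW = time from the rising-limb crossing to
#' the systolic peak, DW = time from the systolic peak to the first
#' falling-limb crossing; crossings are located by linear interpolation
#' between samples.
#'
#' @param cycle A `ppg_cycle`.
#' @param fid Its fiducial set.
#' @param fraction Height fraction (0.25, 0.5 or 0.75 in the standard set).
#' @return Named vector `c(SW, DW, ratio)` in seconds (ratio is unitless);
#'   `NA` if the level is never crossed on a limb.
#' @export
fractional_widths <- function(cycle, fid, fraction) {
  x <- cycle$amplitude
  fs <- fid$sampling_rate
  foot_amp <- x[fid$foot_idx]
  lev <- foot_amp + fraction * (fid$sys_peak_value - foot_amp)
  peak <- fid$sys_peak_idx
  # rising limb: last upward crossing before the peak
  sw <- NA_real_
  up <- which(x[seq_len(peak - 1)] < lev & x[2:peak] >= lev)
  if (length(up)) {
    tc <- cross_time(x, max(up), lev)
    sw <- ((peak - 1) - tc) / fs
  }
  # falling limb: first downward crossing after the peak
  dw <- NA_real_
  n <- length(x)
  if (peak < n) {
    dn <- which(x[peak:(n - 1)] >= lev & x[(peak + 1):n] < lev)
    if (length(dn)) {
      tc <- cross_time(x, peak + min(dn) - 1, lev)
      dw <- (tc - (peak - 1)) / fs
    }
  }
  c(SW = sw, DW = dw, ratio = sw / dw)
}

#' Large artery stiffness index (time-delay form)
#'
#' Time from the systolic to the diastolic peak in seconds; shorter delays
#' indicate stiffer large arteries (earlier wave reflection).
#'
#' @param fid A fiducial set.
#' @return Delay in seconds (`NA` if the diastolic peak is missing).
#' @export
lasi <- function(fid) {
  if (is.na(fid$dia_peak_idx)) return(NA_real_)
  (fid$dia_peak_idx - fid$sys_peak_idx) / fid$sampling_rate
}

#' Augmentation ratio
#'
#' Diastolic peak amplitude over systolic peak amplitude.
#'
#' @param fid A fiducial set.
#' @return A unitless ratio.
#' @export
augmentation <- function(fid) {
  assert_that(fid$sys_peak_value > 0, "systolic peak amplitude must be positive")
  fid$dia_peak_value / fid$sys_peak_value
}

#' Inflection point areas s1-s4
#'
#' Trapezoidal areas under the pulse, partitioned at the maximum-slope
#' point, the systolic peak and the diastolic peak. The four areas sum to
#' the total area under the cycle exactly (shared boundary ordinates).
#'
#' @param cycle A `ppg_cycle`.
#' @param fid Its fiducial set.
#' @return Named vector `c(s1, s2, s3, s4)` in amplitude-seconds.
#' @export
ipa <- function(cycle, fid) {
  x <- cycle$amplitude
  fs <- fid$sampling_rate
  trap <- function(i0, i1) {
    if (i1 <= i0) return(0)
    idx <- i0:i1
    sum((x[idx[-length(idx)]] + x[idx[-1]]) / 2) / fs
  }
  b <- sort(c(fid$foot_idx, fid$max_slope_idx, fid$sys_peak_idx,
              fid$dia_peak_idx, length(x)))
  c(s1 = trap(b[1], b[2]), s2 = trap(b[2], b[3]),
    s3 = trap(b[3], b[4]), s4 = trap(b[4], b[5]))
}

#' Wavelet coefficient statistics of a cycle
#'
#' The cycle is linearly resampled to a fixed dyadic length (128 samples
#' by default) so coefficient vectors are length-stable and
#' sampling-rate-invariant, then decomposed with a 4-level periodized
#' orthogonal DWT; max/min/mean/std of the approximation (`cA4`) and each
#' detail band (`cD1`..`cD4`) are returned.
#'
#' @param cycle A `ppg_cycle`.
#' @param wavelet Wavelet family (default `"db4"`).
#' @param n_resample Dyadic resample length; set `NA` to run at native
#'   rate (then the cycle length itself must satisfy the DWT constraints).
#' @return Named vector of 20 statistics (`cA4_max`, ..., `cD4_std`).
#' @export
dwt_features <- function(cycle, wavelet = "db4", n_resample = 128L) {
  x <- cycle$amplitude
  if (!is.na(n_resample)) {
    x <- approx(seq_along(x), x, n = n_resample)$y
  }
  d <- dwt_multilevel(x, levels = 4, wavelet = wavelet)
  stats <- purrr::imap(d, function(v, nm) {
    setNames(c(max(v), min(v), mean(v), sd(v)),
             paste0(nm, c("_max", "_min", "_mean", "_std")))
  })
  unlist(unname(stats))
}

#' The feature registry
#'
#' Every feature the extractor emits, in stable order: 46 signal features
#' (11 basic, 9 width, LASI + augmentation, 4 areas, 20 wavelet
#' statistics) and 5 demographics.
#'
#' @return A tibble `(name, group)`.
#' @export
feature_registry <- function() {
  sig <- c(
    "period", "mean", "STD", "RMS", "max_slope_idx", "max_slope_value",
    "sys_period", "dia_period", "dia_peak_idx", "dia_peak_value", "fisher",
    "SW25", "SW50", "SW75", "DW25", "DW50", "DW75",
    "ratio25", "ratio50", "ratio75",
    "LASI", "augmentation",
    "s1", "s2", "s3", "s4",
    paste0(rep(c("cA4", "cD1", "cD2", "cD3", "cD4"), each = 4),
           c("_max", "_min", "_mean", "_std"))
  )
  dem <- c("age", "height", "weight", "gender", "bmi")
  tibble(
    name = c(sig, dem),
    group = c(rep("basic", 11), rep("width", 9), rep("amplitude", 2),
              rep("area", 4), rep("wavelet", 20), rep("demographic", 5))
  )
}

#' Extract the full feature vector from one cycle
#'
#' @param cycle A `ppg_cycle`.
#' @param subject Optional single-row tibble/list with `age`, `height`,
#'   `weight`, `sex` (`"M"`/`"F"`) and `bmi`.
#' @param wavelet,n_resample Passed to [dwt_features()].
#' @param max_missing_frac Reject the cycle (error) if more than this
#'   fraction of signal features is missing.
#' @return A one-row tibble in [feature_registry()] order (demographics
#'   `NA` when `subject` is `NULL`).
#' @export
extract_cycle_features <- function(cycle, subject = NULL,
                                   wavelet = "db4", n_resample = 128L,
                                   max_missing_frac = 0.2) {
  fid <- detect_fiducials(cycle)
  w <- purrr::map(c(0.25, 0.5, 0.75),
                  ~ fractional_widths(cycle, fid, .x))
  widths <- c(SW25 = w[[1]][["SW"]], SW50 = w[[2]][["SW"]],
              SW75 = w[[3]][["SW"]],
              DW25 = w[[1]][["DW"]], DW50 = w[[2]][["DW"]],
              DW75 = w[[3]][["DW"]],
              ratio25 = w[[1]][["ratio"]], ratio50 = w[[2]][["ratio"]],
              ratio75 = w[[3]][["ratio"]])
  vals <- c(
    basic_stats(cycle, fid),
    widths,
    LASI = lasi(fid),
    augmentation = augmentation(fid),
    ipa(cycle, fid),
    dwt_features(cycle, wavelet, n_resample)
  )
  miss <- mean(!is.finite(vals))
  assert_that(miss <= max_missing_frac,
              sprintf("cycle rejected: %.0f%% of features missing", 100 * miss))
  dem <- c(age = NA_real_, height = NA_real_, weight = NA_real_,
           gender = NA_real_, bmi = NA_real_)
  if (!is.null(subject)) {
    s <- as.list(subject)
    dem <- c(age = s$age, height = s$height, weight = s$weight,
             gender = as.numeric(identical(s$sex, "M") || identical(s$sex, 1)),
             bmi = s$bmi)
  }
  out <- c(vals, dem)
  as_tibble(as.list(out[feature_registry()$name]))
}

#' Extract features for every segment of a preprocessed table
#'
#' Takes the quality-gated segment table, segments each PPG trace into
#' complete cycles, and extracts the feature vector of the first complete
#' cycle of each segment (single-cycle pulse wave analysis). Demographics
#' are joined from the subject table.
#'
#' @param segments Output of [preprocess_segments()].
#' @param subjects Tibble from [generate_subjects()] (or equivalent with
#'   `subject_id`, `age`, `height`, `weight`, `sex`, `bmi`, `sbp`, `dbp`).
#' @param ... Passed to [extract_cycle_features()].
#' @return A tibble: `subject_id`, `segment_id`, all registry features,
#'   and (when present in `subjects`) reference `sbp`, `dbp`,
#'   `hypertensive`. Segments whose extraction fails are dropped with a
#'   count in `attr(, "n_failed")`.
#' @export
extract_features <- function(segments, subjects, ...) {
  sub_idx <- split(seq_len(nrow(subjects)), subjects$subject_id)
  failed <- 0L
  rows <- purrr::map(seq_len(nrow(segments)), function(i) {
    seg <- segments$segment[[i]]
    sid <- segments$subject_id[i]
    cyc <- segment_cycles(seg)
    if (!nrow(cyc)) { failed <<- failed + 1L; return(NULL) }
    subject <- subjects[sub_idx[[sid]][1], ]
    fv <- tryCatch(
      extract_cycle_features(cyc$cycle[[1]], subject = subject, ...),
      ppgbp_error = function(e) NULL, error = function(e) NULL)
    if (is.null(fv)) { failed <<- failed + 1L; return(NULL) }
    extra <- subject[intersect(c("sbp", "dbp", "hypertensive"),
                               names(subject))]
    bind_cols(tibble(subject_id = sid, segment_id = segments$segment_id[i]),
              fv, extra)
  })
  out <- bind_rows(purrr::compact(rows))
  attr(out, "n_failed") <- failed
  out
}
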