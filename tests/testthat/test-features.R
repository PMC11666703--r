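clean_cycle <- function(seed = 1, heart_rate = 75, sbp = 120, dbp = 70,
                        fs = 125) {
  seg <- normalize_segment(make_clean_segment(seed, heart_rate, sbp, dbp, fs))
  segment_cycles(seg)$cycle[[1]]
}

test_that("fiducial detection recovers the generator's landmarks", {
  fs <- 125
  seg <- normalize_segment(make_clean_segment(heart_rate = 75))
  tr <- attr(seg, "truth")
  cyc <- segment_cycles(seg)
  fid <- detect_fiducials(cyc$cycle[[1]])
  sys_rel <- tr$sys_peak_times[1] - tr$foot_times[1]
  dia_rel <- tr$dia_peak_times[1] - tr$foot_times[1]
  foot_off <- (cyc$foot_idx[1] - 1) / fs    # cycle origin in segment time
  expect_lte(abs((fid$sys_peak_idx - 1) / fs + foot_off - sys_rel), 1 / fs)
  expect_lte(abs((fid$dia_peak_idx - 1) / fs + foot_off - dia_rel), 1 / fs)
  expect_false(fid$dia_peak_inflection)
})

test_that("a pulse without a secondary maximum falls back to inflection", {
  tri <- make_triangle_cycle(apex_frac = 0.3)
  fid <- detect_fiducials(tri)
  expect_true(fid$dia_peak_inflection)
  expect_gt(fid$dia_peak_idx, fid$sys_peak_idx)
})

test_that("fiducial ordering holds across 1000 random generator draws", {
  cfg <- synth_config(seed = 33, n_subjects = 1000)
  subs <- generate_subjects(cfg)
  p <- bp_to_pulse_params(subs, cfg)
  ok <- vapply(seq_len(nrow(p)), function(i) {
    per <- p$period[i]
    fs <- 125
    n <- round(per * fs)
    t <- (0:(n - 1)) / fs
    prm <- as.list(p[i, ])
    # one period starting at the pulse foot
    lm <- ppgbp:::pulse_phase_landmarks(prm)
    x <- ppgbp:::pulse_train(t + lm$foot, prm)
    x <- (x - min(x)) / (max(x) - min(x))
    fid <- tryCatch(detect_fiducials(new_ppg_cycle(x, fs)),
                    error = function(e) NULL)
    if (is.null(fid)) return(FALSE)
    fid$foot_idx < fid$max_slope_idx &&
      fid$max_slope_idx < fid$sys_peak_idx &&
      fid$sys_peak_idx < fid$dia_peak_idx &&
      fid$dia_peak_idx <= length(x)
  }, logical(1))
  expect_true(all(ok))
})

test_that("fisher skewness matches direct evaluation and is antisymmetric", {
  expect_equal(fisher_skewness(1:5), 0)
  expect_equal(fisher_skewness(c(0, 0, 0, 4)), 24 / (4 * 3^1.5))
  set.seed(1)
  x <- rnorm(50)
  expect_equal(fisher_skewness(-x), -fisher_skewness(x))
  expect_error(fisher_skewness(rep(2, 10)), "constant")
})

test_that("basic statistics agree with hand arithmetic", {
  cyc <- new_ppg_cycle(c(0, 1, 0, 0, 0, 0, 0, 0), 8)
  fid <- detect_fiducials(cyc)
  bs <- basic_stats(cyc, fid)
  expect_equal(bs[["period"]], 1)
  expect_equal(bs[["mean"]], 0.125)
  expect_equal(bs[["RMS"]], sqrt(1 / 8))
  expect_lte(abs(bs[["sys_period"]] + bs[["dia_period"]] -
                   bs[["period"]]), 1 / 8 + 1e-12)
  # two-pass STD oracle
  x <- cyc$amplitude
  expect_equal(bs[["STD"]], sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
})

test_that("fractional widths follow triangle geometry", {
  iso <- make_triangle_cycle(fs = 200, apex_frac = 0.5)
  fid <- detect_fiducials(iso)
  w50 <- fractional_widths(iso, fid, 0.5)
  expect_equal(w50[["SW"]], 0.25, tolerance = 1e-6)
  expect_equal(w50[["DW"]], 0.25, tolerance = 1e-6)
  expect_equal(w50[["ratio"]], 1, tolerance = 1e-6)
  skew <- make_triangle_cycle(fs = 200, apex_frac = 0.25)
  fid2 <- detect_fiducials(skew)
  w <- fractional_widths(skew, fid2, 0.5)
  expect_equal(w[["SW"]], 0.125, tolerance = 1e-6)
  expect_equal(w[["DW"]], 0.375, tolerance = 1e-6)
  expect_equal(w[["ratio"]], 1 / 3, tolerance = 1e-5)
})

test_that("widths shrink as the height fraction grows on generator pulses", {
  for (seed in 1:5) {
    cyc <- clean_cycle(seed = seed, sbp = 100 + 15 * seed)
    fid <- detect_fiducials(cyc)
    sw <- vapply(c(0.25, 0.5, 0.75),
                 function(f) fractional_widths(cyc, fid, f)[["SW"]],
                 numeric(1))
    expect_true(all(diff(sw) <= 1e-12))
  }
})

test_that("LASI and augmentation recover the generator's morphology", {
  fs <- 125
  seg <- normalize_segment(make_clean_segment(heart_rate = 75, sbp = 120))
  tr <- attr(seg, "truth")
  cyc <- segment_cycles(seg)$cycle[[1]]
  fid <- detect_fiducials(cyc)
  truth_delay <- tr$dia_peak_times[1] - tr$sys_peak_times[1]
  expect_lte(abs(lasi(fid) - truth_delay), 1.5 / fs)
  expect_gt(lasi(fid), 0)
  expect_lt(lasi(fid), nrow(cyc) / fs)
  # augmentation in (0,1] across a sweep, and monotone in SBP
  augs <- vapply(c(100, 130, 160), function(s) {
    augmentation(detect_fiducials(clean_cycle(sbp = s)))
  }, numeric(1))
  expect_true(all(augs > 0 & augs <= 1))
  expect_true(all(diff(augs) > 0))
})

test_that("augmentation is the simple peak ratio", {
  fid <- list(sys_peak_value = 0.8, dia_peak_value = 0.4)
  expect_equal(augmentation(fid), 0.5)
  fid_eq <- list(sys_peak_value = 0.6, dia_peak_value = 0.6)
  expect_equal(augmentation(fid_eq), 1)
})

test_that("inflection point areas partition the total area", {
  cyc <- clean_cycle(seed = 2)
  fid <- detect_fiducials(cyc)
  s <- ipa(cyc, fid)
  # independent trapezoid oracle over the full cycle
  x <- cyc$amplitude
  total <- 0
  for (i in seq_len(length(x) - 1)) total <- total + (x[i] + x[i + 1]) / 2
  total <- total / 125
  expect_equal(sum(s), total, tolerance = 1e-9)
  # rectangle pulse split at quarter points -> four equal areas
  rect <- new_ppg_cycle(rep(1, 33), 32)
  fake_fid <- list(foot_idx = 1L, max_slope_idx = 9L, sys_peak_idx = 17L,
                   dia_peak_idx = 25L, sampling_rate = 32)
  sr <- ipa(rect, fake_fid)
  expect_equal(unname(sr), rep(0.25, 4), tolerance = 1e-12)
})

test_that("wavelet statistics conserve energy and handle constants", {
  cyc <- clean_cycle(seed = 3)
  x128 <- approx(seq_len(nrow(cyc)), cyc$amplitude, n = 128)$y
  d <- dwt_multilevel(x128)
  expect_equal(sum(unlist(d)^2), sum(x128^2), tolerance = 1e-6)
  # constant signal: all detail stats 0, approximation mean > 0
  dc <- dwt_features(new_ppg_cycle(rep(0.4, 64), 64))
  detail <- dc[grepl("^cD", names(dc))]
  expect_lt(max(abs(detail)), 1e-12)
  expect_gt(dc[["cA4_mean"]], 0)
  # deterministic
  expect_identical(dwt_features(cyc), dwt_features(cyc))
  # too-short input names the constraint
  expect_error(dwt_multilevel(rnorm(32), levels = 4), "at least")
})

test_that("the Haar transform matches hand computation", {
  h <- dwt_multilevel(c(1, 2, 3, 4, 0, 0, 2, 2), levels = 1,
                      wavelet = "haar")
  expect_equal(h$cA1, c(3, 7, 0, 4) / sqrt(2))
  expect_equal(h$cD1, c(-1, -1, 0, 0) / sqrt(2))
})

test_that("the feature vector covers the registry exactly once", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 51)
  expect_equal(sum(reg$group != "demographic"), 46)
  cyc <- clean_cycle()
  subj <- list(age = 50, height = 170, weight = 70, sex = "M", bmi = 24.2)
  fv <- extract_cycle_features(cyc, subj)
  expect_identical(names(fv), reg$name)
  expect_false(anyDuplicated(names(fv)) > 0)
  # identical cycles give identical vectors
  expect_identical(fv, extract_cycle_features(cyc, subj))
  expect_equal(fv$gender, 1)
})

test_that("time-unit features are sampling-rate invariant", {
  f1 <- extract_cycle_features(clean_cycle(fs = 125))
  f2 <- extract_cycle_features(clean_cycle(fs = 250))
  for (nm in c("period", "sys_period", "dia_period", "LASI", "SW50",
               "DW50", "augmentation")) {
    expect_lt(abs(f1[[nm]] - f2[[nm]]), 2 / 125)
  }
})
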