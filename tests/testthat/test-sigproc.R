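test_that("the magnitude spectrum localises tones correctly", {
  fs <- 125
  t <- (0:(fs * 8 - 1)) / fs
  seg <- new_ppg_segment(sin(2 * pi * 1.5 * t), fs)
  sp <- compute_spectrum(seg)
  expect_equal(sp$frequency_hz[which.max(sp$magnitude)], 1.5,
               tolerance = 1 / 8)
  # constant signal: all energy at DC
  spc <- compute_spectrum(new_ppg_segment(rep(2, 64), fs))
  expect_equal(which.max(spc$magnitude), 1L)
  expect_lt(max(spc$magnitude[-1]), 1e-10)
  # two tones -> two dominant non-DC peaks at those bins
  seg2 <- new_ppg_segment(sin(2 * pi * 1.5 * t) + sin(2 * pi * 3 * t), fs)
  sp2 <- compute_spectrum(seg2)
  top2 <- sp2$frequency_hz[order(-sp2$magnitude)][1:2]
  expect_setequal(round(sort(top2), 3), c(1.5, 3))
})

test_that("the band-pass keeps the pass band and rejects DC and noise bands", {
  fs <- 125
  t <- (0:(fs * 10 - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))
  mid <- seq(2 * fs, 8 * fs)           # avoid filter edge transients
  # DC rejection
  dc <- new_ppg_segment(rep(1, length(t)) + 0.01 * sin(2 * pi * 2 * t), fs)
  expect_lt(abs(mean(bandpass(dc)$amplitude[mid])), 0.01)
  # pass-band gain ~ 1 at 2 Hz
  s2 <- new_ppg_segment(sin(2 * pi * 2 * t), fs)
  expect_equal(rms(bandpass(s2)$amplitude[mid]), rms(s2$amplitude[mid]),
               tolerance = 0.05)
  # stop-band attenuation at 50 Hz
  s50 <- new_ppg_segment(sin(2 * pi * 50 * t), fs)
  expect_lt(rms(bandpass(s50)$amplitude[mid]), 0.01 * rms(s50$amplitude[mid]))
  # linearity
  set.seed(1)
  x <- rnorm(500)
  a <- bandpass(new_ppg_segment(3.7 * x, fs))$amplitude
  b <- 3.7 * bandpass(new_ppg_segment(x, fs))$amplitude
  expect_lt(max(abs(a - b)) / max(abs(a)), 1e-9)
  # invalid corner frequency
  expect_error(bandpass(s2, filter_spec(high_cut = 70)), "Nyquist")
})

test_that("min-max normalization maps to [0,1], idempotently", {
  seg <- new_ppg_segment(c(2, 4, 6), 10)
  n1 <- normalize_segment(seg)
  expect_equal(n1$amplitude, c(0, 0.5, 1))
  expect_equal(normalize_segment(n1)$amplitude, n1$amplitude)
  set.seed(2)
  r <- normalize_segment(new_ppg_segment(rnorm(100), 10))
  expect_identical(range(r$amplitude), c(0, 1))
  # order preservation
  expect_identical(order(r$amplitude),
                   order(normalize_segment(r)$amplitude))
  expect_error(normalize_segment(new_ppg_segment(rep(1, 5), 10)),
               "constant")
})

test_that("S-SQI matches the skewness formula and ranks quality", {
  # symmetric triangle wave -> zero skewness
  tri <- c(seq(0, 1, by = 0.05), seq(0.95, 0.05, by = -0.05))
  tri <- rep(tri, 5)
  expect_equal(ssqi(new_ppg_segment(tri, 40)), 0, tolerance = 1e-9)
  # direct formula oracle on [1,1,1,7]
  expect_equal(ssqi(new_ppg_segment(c(1, 1, 1, 7), 4)),
               81 / (4 * 6.75^1.5))
  # clean pulse beats the same pulse drowned in noise
  seg <- make_clean_segment(seed = 4)
  set.seed(4)
  noisy <- new_ppg_segment(seg$amplitude + rnorm(nrow(seg), 0, 0.5), 125)
  expect_gt(ssqi(seg), ssqi(noisy))
  expect_error(ssqi(new_ppg_segment(rep(1, 10), 10)), "constant")
})

test_that("quality gating keeps clean pulses and is monotone in threshold", {
  cfg <- quiet_config(seed = 6, n_subjects = 10, segments_per_subject = 1)
  ds <- generate_ppg_dataset(cfg)
  set.seed(8)
  noise_rows <- purrr::map(1:5, function(i) {
    tibble::tibble(subject_id = paste0("N", i),
                   segment_id = paste0("N", i, "_seg01"),
                   segment = list(new_ppg_segment(rnorm(262), 125)))
  })
  segs <- dplyr::bind_rows(ds$segments, dplyr::bind_rows(noise_rows)) |>
    dplyr::mutate(segment = purrr::map(segment, normalize_segment))
  kept <- quality_filter(segs, threshold = 0.3)
  expect_equal(nrow(kept), 10)
  expect_true(all(startsWith(kept$subject_id, "S")))
  expect_equal(nrow(quality_filter(segs, -Inf)),
               sum(purrr::map_int(segs$segment,
                                  ~ nrow(segment_cycles(.x))) >= 1))
  expect_equal(nrow(quality_filter(segs, Inf)), 0)
  # monotone: raising the threshold never adds segments
  n_at <- vapply(c(-1, 0, 0.3, 0.6, 1),
                 function(th) nrow(quality_filter(segs, th)), numeric(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("cycle segmentation recovers the generator's feet", {
  seg <- normalize_segment(make_clean_segment(heart_rate = 75))
  cyc <- segment_cycles(seg)
  expect_equal(nrow(cyc), 2)
  truth_feet_idx <- attr(seg, "truth")$foot_times * 125 + 1
  expect_lte(max(abs(cyc$foot_idx - truth_feet_idx[1:2])), 1)
  expect_lte(abs(cyc$end_idx[2] - truth_feet_idx[3]), 1)
  # constant signal -> no cycles
  expect_equal(nrow(segment_cycles(new_ppg_segment(rep(0.5, 300), 125))), 0)
})

test_that("the preprocessing chain is reproducible", {
  cfg <- synth_config(seed = 21, n_subjects = 3)
  ds <- generate_ppg_dataset(cfg)
  a <- preprocess_segments(ds$segments)
  b <- preprocess_segments(ds$segments)
  expect_identical(a$sqi, b$sqi)
  expect_s3_class(attr(a, "rejection_log"), "data.frame")
})
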