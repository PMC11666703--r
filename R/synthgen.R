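# Synthetic PPG study generator: seeded subjects with realistic demographics,
# a monotone BP -> pulse-morphology mapping, and two-Gaussian pulse trains.

# Demographic calibration targets (mean, sd) used as generator defaults.
DEMOGRAPHIC_TARGETS <- list(
  age         = c(mean = 57.42,  sd = 15.98, lo = 18,  hi = 100),
  height      = c(mean = 161.44, sd = 8.82,  lo = 120, hi = 210),
  bmi         = c(mean = 22.83,  sd = 3.93,  lo = 15,  hi = 40),
  heart_rate  = c(mean = 74.94,  sd = 10.24, lo = 40,  hi = 120),
  sbp         = c(mean = 128.75, sd = 20.64, lo = NA,  hi = NA),
  dbp         = c(mean = 71.73,  sd = 11.30, lo = NA,  hi = NA)
)
MALE_FRACTION <- 0.5355

# Linear BP model coefficients (per year of age, per kg/m^2 of BMI).
BP_COEF <- list(
  sbp = c(age = 0.45, bmi = 1.2),
  dbp = c(age = 0.08, bmi = 0.2),
  noise_cor = 0.5
)

#' Configuration for the synthetic PPG study generator
#'
#' Bundles every knob of the generator: cohort size, sampling rate, segment
#' duration, additive noise levels, and the target hypertension prevalence.
#' On construction the SBP/DBP intercepts are calibrated (by an internal
#' fixed-seed Monte Carlo draw and root finding) so that the probability of
#' `sbp > 130 | dbp > 80` equals `hypertension_prevalence` in expectation.
#'
#' @param seed Integer seed controlling every random draw downstream.
#' @param n_subjects Number of subjects in the cohort.
#' @param segments_per_subject PPG segments recorded per subject.
#' @param sampling_rate Sampling rate in Hz.
#' @param segment_duration Segment length in seconds (2.1 s holds 2-3 beats).
#' @param noise_sd Standard deviation of additive white noise (amplitude units).
#' @param baseline_wander_amp Amplitude of the ~0.2 Hz respiratory baseline
#'   sinusoid (amplitude units).
#' @param hypertension_prevalence Target fraction of hypertensive subjects.
#' @param morph_noise_sd SD of the jitter added to the BP-linked morphology
#'   parameters (peak-delay fraction and augmentation ratio); 0 makes the
#'   BP -> morphology mapping deterministic.
#' @return A list of class `synth_config`.
#' @examples
#' cfg <- synth_config(seed = 1, n_subjects = 10)
#' @export
synth_config <- function(seed = 1L,
                         n_subjects = 219L,
                         segments_per_subject = 3L,
                         sampling_rate = 125,
                         segment_duration = 2.1,
                         noise_sd = 0.02,
                         baseline_wander_amp = 0.05,
                         hypertension_prevalence = 0.1967,
                         morph_noise_sd = 0.02) {
  assert_that(n_subjects >= 1 && segments_per_subject >= 1,
              "counts must be positive")
  assert_that(sampling_rate > 0 && segment_duration > 0,
              "sampling_rate and segment_duration must be positive")
  assert_that(hypertension_prevalence > 0 && hypertension_prevalence < 1,
              "hypertension_prevalence must be in (0,1)")
  cfg <- structure(list(
    seed = as.integer(seed),
    n_subjects = as.integer(n_subjects),
    segments_per_subject = as.integer(segments_per_subject),
    sampling_rate = sampling_rate,
    segment_duration = segment_duration,
    noise_sd = noise_sd,
    baseline_wander_amp = baseline_wander_amp,
    hypertension_prevalence = hypertension_prevalence,
    morph_noise_sd = morph_noise_sd
  ), class = "synth_config")
  cfg$bp_shift <- calibrate_bp_shift(hypertension_prevalence)
  cfg
}

# Residual BP noise SDs chosen so marginal SDs match the demographic targets.
bp_noise_sd <- function() {
  t <- DEMOGRAPHIC_TARGETS
  sig_s <- sqrt(t$sbp[["sd"]]^2 -
                  (BP_COEF$sbp[["age"]] * t$age[["sd"]])^2 -
                  (BP_COEF$sbp[["bmi"]] * t$bmi[["sd"]])^2)
  sig_d <- sqrt(t$dbp[["sd"]]^2 -
                  (BP_COEF$dbp[["age"]] * t$age[["sd"]])^2 -
                  (BP_COEF$dbp[["bmi"]] * t$bmi[["sd"]])^2)
  c(sbp = sig_s, dbp = sig_d)
}

# Draw SBP/DBP given demographics; `shift` lowers both means (scaled by the
# marginal SD ratio for DBP) to hit the configured prevalence.
draw_bp <- function(age, bmi, shift) {
  t <- DEMOGRAPHIC_TARGETS
  sig <- bp_noise_sd()
  rho <- BP_COEF$noise_cor
  n <- length(age)
  z0 <- rnorm(n); z1 <- rnorm(n); z2 <- rnorm(n)
  a <- sqrt(rho); b <- sqrt(1 - rho)
  eps_s <- sig[["sbp"]] * (a * z0 + b * z1)
  eps_d <- sig[["dbp"]] * (a * z0 + b * z2)
  sbp <- t$sbp[["mean"]] - shift +
    BP_COEF$sbp[["age"]] * (age - t$age[["mean"]]) +
    BP_COEF$sbp[["bmi"]] * (bmi - t$bmi[["mean"]]) + eps_s
  dbp <- t$dbp[["mean"]] - shift * t$dbp[["sd"]] / t$sbp[["sd"]] +
    BP_COEF$dbp[["age"]] * (age - t$age[["mean"]]) +
    BP_COEF$dbp[["bmi"]] * (bmi - t$bmi[["mean"]]) + eps_d
  sbp <- clamp(sbp, 70, 230)
  dbp <- clamp(pmin(dbp, sbp - 10), 35, 140)
  list(sbp = sbp, dbp = dbp)
}

draw_demographics <- function(n) {
  t <- DEMOGRAPHIC_TARGETS
  age <- rtruncnorm(n, t$age[["mean"]], t$age[["sd"]],
                    t$age[["lo"]], t$age[["hi"]])
  height <- rtruncnorm(n, t$height[["mean"]], t$height[["sd"]],
                       t$height[["lo"]], t$height[["hi"]])
  bmi <- rtruncnorm(n, t$bmi[["mean"]], t$bmi[["sd"]],
                    t$bmi[["lo"]], t$bmi[["hi"]])
  hr <- rtruncnorm(n, t$heart_rate[["mean"]], t$heart_rate[["sd"]],
                   t$heart_rate[["lo"]], t$heart_rate[["hi"]])
  list(age = age, height = height, bmi = bmi, heart_rate = hr,
       weight = bmi * (height / 100)^2)
}

# Solve for the common mean shift that yields the requested hypertension
# prevalence, on a fixed-seed Monte Carlo draw (independent of the user RNG).
calibrate_bp_shift <- function(prevalence, n_mc = 100000L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(860515L)
  dem <- draw_demographics(n_mc)
  prev_at <- function(shift) {
    bp <- draw_bp(dem$age, dem$bmi, shift)
    mean(label_hypertension(bp$sbp, bp$dbp)) - prevalence
  }
  # prev_at reuses the cached demographics but draws fresh BP noise; reseed
  # inside for a smooth, deterministic objective.
  obj <- function(shift) { set.seed(911847L); prev_at(shift) }
  uniroot(obj, c(-40, 80), tol = 1e-3)$root
}

#' Generate a cohort of synthetic subjects
#'
#' Demographics are drawn from truncated normal distributions matching the
#' generator's calibration targets (age 57.42 +/- 15.98 y, height
#' 161.44 +/- 8.82 cm, BMI 22.83 +/- 3.93 kg/m^2, heart rate
#' 74.94 +/- 10.24 bpm, 53.55% male); weight is derived from BMI and height
#' so the BMI invariant holds by construction. SBP and DBP follow a linear
#' model in age and BMI plus correlated noise, with intercepts calibrated so
#' the configured hypertension prevalence (`sbp > 130 | dbp > 80`) is met in
#' expectation.
#'
#' @param config A [synth_config()].
#' @param n Number of subjects (defaults to `config$n_subjects`).
#' @return A tibble with one row per subject: `subject_id`, `age`, `height`,
#'   `weight`, `sex`, `bmi`, `heart_rate`, `sbp`, `dbp`, `hypertensive`.
#' @examples
#' generate_subjects(synth_config(seed = 7, n_subjects = 5))
#' @export
generate_subjects <- function(config, n = config$n_subjects) {
  assert_that(inherits(config, "synth_config"), "config must be a synth_config")
  set.seed(config$seed)
  draw_subjects(config, n)
}

# Internal: draws using the *current* RNG state (no reseeding).
draw_subjects <- function(config, n) {
  dem <- draw_demographics(n)
  bp <- draw_bp(dem$age, dem$bmi, config$bp_shift)
  sex <- ifelse(runif(n) < MALE_FRACTION, "M", "F")
  tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = dem$age, height = dem$height, weight = dem$weight,
    sex = sex, bmi = dem$bmi, heart_rate = dem$heart_rate,
    sbp = bp$sbp, dbp = bp$dbp,
    hypertensive = label_hypertension(bp$sbp, bp$dbp)
  )
}

#' Map blood pressure to pulse morphology parameters
#'
#' Encodes the working assumption that single-cycle PPG morphology carries
#' BP information: higher SBP shortens the systolic-to-diastolic peak delay
#' (a stiffness surrogate, smaller LASI) and raises the augmentation ratio;
#' higher DBP widens the diastolic (reflected) wave. The mapping is linear
#' with clamping, plus optional Gaussian jitter (`morph_noise_sd`), and the
#' pulse period is `60 / heart_rate`.
#'
#' @param subjects Tibble from [generate_subjects()] (needs `heart_rate`,
#'   `sbp`, `dbp`).
#' @param config A [synth_config()]; `config$morph_noise_sd` sets the jitter.
#' @param morph_noise_sd Override for the jitter SD (0 = deterministic).
#' @return The input tibble with columns `period`, `systolic_amp`,
#'   `systolic_center`, `systolic_width`, `diastolic_amp`,
#'   `diastolic_center`, `diastolic_width`, `delay_frac`, `aug_ratio` added.
#' @export
bp_to_pulse_params <- function(subjects, config,
                               morph_noise_sd = config$morph_noise_sd) {
  t <- DEMOGRAPHIC_TARGETS
  n <- nrow(subjects)
  period <- 60 / subjects$heart_rate
  # keep the delay below half the period so the inter-beat trough is always
  # deeper than the systolic-diastolic notch (the foot stays the global min)
  delay <- 0.36 - 0.0012 * (subjects$sbp - t$sbp[["mean"]])
  aug <- 0.38 + 0.0040 * (subjects$sbp - t$sbp[["mean"]])
  dwf <- 0.090 + 0.0020 * (subjects$dbp - t$dbp[["mean"]])
  if (morph_noise_sd > 0) {
    delay <- delay + rnorm(n, 0, morph_noise_sd)
    aug <- aug + rnorm(n, 0, morph_noise_sd)
    dwf <- dwf + rnorm(n, 0, morph_noise_sd / 4)
  }
  delay <- clamp(delay, 0.27, 0.45)
  aug <- clamp(aug, 0.10, 0.80)
  dwf <- clamp(dwf, 0.05, 0.18)
  subjects %>%
    mutate(
      period = period,
      systolic_amp = 1,
      systolic_center = 0.18 * period,
      systolic_width = 0.07 * period,
      diastolic_amp = aug,
      diastolic_center = (0.18 + delay) * period,
      diastolic_width = dwf * period,
      delay_frac = delay,
      aug_ratio = aug
    )
}

# Evaluate the noiseless periodic pulse train at times t (seconds).
pulse_train <- function(t, p) {
  k <- seq(floor(min(t) / p$period) - 2, ceiling(max(t) / p$period) + 2)
  z <- numeric(length(t))
  for (kk in k) {
    z <- z +
      p$systolic_amp *
        exp(-(t - p$systolic_center - kk * p$period)^2 /
              (2 * p$systolic_width^2)) +
      p$diastolic_amp *
        exp(-(t - p$diastolic_center - kk * p$period)^2 /
              (2 * p$diastolic_width^2))
  }
  z
}

# Phase landmarks of one period of the noiseless train, on a fine grid:
# foot (global minimum), systolic peak (global maximum) and diastolic peak
# (second local maximum, NA if the two waves merge into one mode).
pulse_phase_landmarks <- function(p, n_grid = 4000L) {
  ph <- seq(0, p$period, length.out = n_grid + 1L)[seq_len(n_grid)]
  z <- pulse_train(ph, p)
  t_foot <- ph[which.min(z)]
  # local maxima on the circular grid
  zl <- c(z[n_grid], z[-n_grid]); zr <- c(z[-1], z[1])
  imax <- which(z > zl & z >= zr)
  t_smax <- ph[imax[which.max(z[imax])]]
  t_dmax <- NA_real_
  if (length(imax) >= 2) {
    rest <- imax[ph[imax] != t_smax]
    t_dmax <- ph[rest[which.max(z[rest])]]
  }
  list(foot = t_foot, sys = t_smax, dia = t_dmax)
}

#' Synthesize one PPG segment from pulse parameters
#'
#' Builds `segment_duration * sampling_rate` samples of a repeated
#' two-Gaussian pulse (systolic wave + reflected diastolic wave), phased so
#' the segment starts at a pulse foot, plus a ~0.2 Hz baseline-wander
#' sinusoid and white Gaussian noise. The analytic ground-truth fiducial
#' times of every complete cycle are attached for round-trip testing.
#'
#' @param params One row of [bp_to_pulse_params()] output (list or 1-row
#'   tibble with the pulse parameter columns).
#' @param config A [synth_config()].
#' @return A `ppg_segment`: tibble `(time_s, amplitude)` with attributes
#'   `sampling_rate`, `subject_id` and `truth` (list with `foot_times`,
#'   `sys_peak_times`, `dia_peak_times`, `period`, `delay_frac`,
#'   `aug_ratio`).
#' @export
synthesize_segment <- function(params, config) {
  p <- as.list(params)
  assert_that(config$segment_duration >= p$period,
              "segment shorter than one pulse period")
  fs <- config$sampling_rate
  n <- round(config$segment_duration * fs)
  t <- (seq_len(n) - 1) / fs
  lm <- pulse_phase_landmarks(p)
  # shift phase so t = 0 sits at the pulse foot
  z <- pulse_train(t + lm$foot, p)
  wander_phase <- runif(1, 0, 2 * pi)
  seg <- z +
    config$baseline_wander_amp * sin(2 * pi * 0.2 * t + wander_phase) +
    rnorm(n, 0, config$noise_sd)
  dur <- config$segment_duration
  feet <- seq(0, dur, by = p$period)
  feet <- feet[feet <= dur]
  n_cycles <- max(0L, sum(feet + p$period <= dur + 1e-9))
  rel <- function(x) (x - lm$foot) %% p$period
  sys_t <- rel(lm$sys) + (seq_len(n_cycles) - 1) * p$period
  dia_t <- if (is.na(lm$dia)) rep(NA_real_, n_cycles) else
    rel(lm$dia) + (seq_len(n_cycles) - 1) * p$period
  new_ppg_segment(
    seg, fs, subject_id = p$subject_id %||% NA_character_,
    truth = list(
      foot_times = feet[seq_len(n_cycles + 1L)],
      sys_peak_times = sys_t, dia_peak_times = dia_t,
      period = p$period, delay_frac = p$delay_frac %||% NA_real_,
      aug_ratio = p$aug_ratio %||% NA_real_
    )
  )
}

#' Generate a complete synthetic PPG study
#'
#' One seeded call producing the whole study: a subject cohort, per-subject
#' pulse morphology parameters, and `segments_per_subject` PPG segments per
#' subject. Identical `config` (including seed) reproduces the dataset
#' exactly.
#'
#' @param config A [synth_config()].
#' @return A list of class `ppg_dataset` with elements `subjects` (tibble)
#'   and `segments` (tibble with `subject_id`, `segment_id` and a `segment`
#'   list-column of `ppg_segment` objects).
#' @examples
#' ds <- generate_ppg_dataset(synth_config(seed = 1, n_subjects = 3))
#' ds$segments
#' @export
generate_ppg_dataset <- function(config) {
  assert_that(inherits(config, "synth_config"), "config must be a synth_config")
  set.seed(config$seed)
  subjects <- draw_subjects(config, config$n_subjects)
  params <- bp_to_pulse_params(subjects, config)
  rows <- purrr::map(seq_len(nrow(params)), function(i) {
    purrr::map(seq_len(config$segments_per_subject), function(j) {
      seg <- synthesize_segment(params[i, ], config)
      tibble(subject_id = params$subject_id[i],
             segment_id = sprintf("%s_seg%02d", params$subject_id[i], j),
             segment = list(seg))
    })
  })
  segments <- bind_rows(purrr::flatten(rows))
  structure(list(subjects = subjects, params = params, segments = segments,
                 config = config),
            class = "ppg_dataset")
}

#' @export
print.ppg_dataset <- function(x, ...) {
  cat("<ppg_dataset> ", nrow(x$subjects), " subjects, ",
      nrow(x$segments), " segments @ ", x$config$sampling_rate, " Hz\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Subjects go to `subjects.csv`; each segment to
#' `<segment_id>.csv` (`time_s,amplitude`) with a JSON sidecar
#' (`<segment_id>.json`) carrying `sampling_rate` and `subject_id`.
#'
#' @param dataset A `ppg_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ppg_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(dataset$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  purrr::pwalk(dataset$segments, function(subject_id, segment_id, segment) {
    utils::write.csv(as.data.frame(segment[c("time_s", "amplitude")]),
                     file.path(dir, paste0(segment_id, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(sampling_rate = attr(segment, "sampling_rate"),
           subject_id = subject_id),
      file.path(dir, paste0(segment_id, ".json")), auto_unbox = TRUE)
  })
  invisible(dir)
}

#' Read one PPG segment written by [write_ppg_dataset()]
#' @param csv_path Path to the `time_s,amplitude` CSV.
#' @param sidecar_path JSON sidecar path; defaults to `csv_path` with
#'   `.json` extension.
#' @return A `ppg_segment`.
#' @export
read_ppg_segment <- function(csv_path,
                             sidecar_path = sub("\\.csv$", ".json", csv_path)) {
  assert_that(file.exists(csv_path), paste("no such file:", csv_path))
  d <- utils::read.csv(csv_path)
  meta <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path) else list()
  fs <- meta$sampling_rate %||%
    (1 / median(diff(d$time_s)))
  new_ppg_segment(d$amplitude, fs,
                  subject_id = meta$subject_id %||% NA_character_)
}
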