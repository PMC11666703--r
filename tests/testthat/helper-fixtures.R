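# Shared fixtures, all generated in code.

# A triangular pulse cycle: base `dur` seconds, apex at `apex_frac` of it.
make_triangle_cycle <- function(fs = 100, dur = 1, apex_frac = 0.5,
                                height = 1) {
  n <- round(dur * fs) + 1
  t <- (seq_len(n) - 1) / fs
  apex <- apex_frac * dur
  amp <- ifelse(t <= apex, height * t / apex,
                height * (dur - t) / (dur - apex))
  amp[n] <- 0
  new_ppg_cycle(amp, fs)
}

# Noise-free synthetic config (fixed small cohort).
quiet_config <- function(seed = 1, n_subjects = 5, ...) {
  synth_config(seed = seed, n_subjects = n_subjects, noise_sd = 0,
               baseline_wander_amp = 0, morph_noise_sd = 0, ...)
}

# One noiseless segment for a subject with a given heart rate / BP.
make_clean_segment <- function(seed = 1, heart_rate = 75, sbp = 120,
                               dbp = 70, fs = 125) {
  cfg <- quiet_config(seed = seed, sampling_rate = fs)
  subj <- tibble::tibble(subject_id = "T1", age = 50, height = 170,
                         weight = 70, sex = "M", bmi = 24.2,
                         heart_rate = heart_rate, sbp = sbp, dbp = dbp)
  p <- bp_to_pulse_params(subj, cfg, morph_noise_sd = 0)
  set.seed(seed)
  synthesize_segment(p[1, ], cfg)
}

# A small labelled feature set with the study's 108:441 class imbalance.
make_imbalanced_data <- function(seed = 1, n_pos = 108, n_neg = 441,
                                 p = 4) {
  set.seed(seed)
  x <- tibble::as_tibble(as.data.frame(matrix(rnorm((n_pos + n_neg) * p),
                                              ncol = p)))
  names(x) <- paste0("f", seq_len(p))
  list(data = x, labels = c(rep(TRUE, n_pos), rep(FALSE, n_neg)))
}

# Independent pairwise AUC oracle: P(score+ > score-) + 0.5 P(tie).
pairwise_auc <- function(truth, scores) {
  sp <- scores[truth]; sn <- scores[!truth]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}

# Brute-force impurity-decrease oracle: walks a cart_tree from the root,
# re-deriving every node's sample partition from the data and re-measuring
# impurities from scratch.
oracle_importance <- function(tree, data, y, task) {
  imp_fun <- if (task == "classification") {
    function(v) { p <- table(v) / length(v); 1 - sum(p^2) }
  } else {
    function(v) mean((v - mean(v))^2)
  }
  N <- tree$n
  acc <- stats::setNames(numeric(length(tree$features)), tree$features)
  rec <- function(node, idx) {
    if (node$is_leaf) return(invisible(NULL))
    left <- idx[data[[node$feature]][idx] <= node$threshold]
    right <- setdiff(idx, left)
    delta <- (length(idx) / N) *
      (imp_fun(y[idx]) -
         length(right) / length(idx) * imp_fun(y[right]) -
         length(left) / length(idx) * imp_fun(y[left]))
    acc[node$feature] <<- acc[node$feature] + delta
    rec(node$left, left)
    rec(node$right, right)
  }
  rec(tree$root, seq_len(nrow(data)))
  if (sum(acc) > 0) acc / sum(acc) else acc
}
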