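# Shared fixtures: small synthetic signals built in code at test time.

# IBI ground truth -> knot list usable by resample_ibi()
gt_knots <- function(gt) {
  list(interval_end_s = gt$beat_times_s[-1], intervals_s = gt$ibi_s)
}

# one resampled HRV window of the requested length from a sim config
sim_hrv_window <- function(length_s = 60, ...) {
  cfg <- sim_config(duration_s = length_s + 5, ...)
  gt <- simulate_ibi(cfg)
  cut_windows(resample_ibi(gt_knots(gt)), length_s = length_s)[[1]]
}

# brute-force ROC area: count all between-class pairs, ties credited 0.5
roc_area_brute <- function(pos, neg) {
  wins <- outer(pos, neg, function(p, a) (p > a) + 0.5 * (p == a))
  mean(wins)
}

# per-subject comparison used by the scaled-down study analogue: ROC-area
# distance from chance and best LOO accuracy, for the top wavelet feature
# (entropy of A8) versus the LF/HF ratio
compare_feature_sets <- function(seed, n_subjects = 4) {
  roc_e <- roc_l <- acc_e <- acc_l <- numeric(n_subjects)
  for (s in seq_len(n_subjects)) {
    sub <- simulate_subject(seed * 1000L + s * 100L,
                            subject_id = sprintf("S%d", s))
    roc_e[s] <- abs(roc_area(sub$entropy_A8, sub$label)$roc_area - 0.5)
    roc_l[s] <- abs(roc_area(sub$lf_hf, sub$label)$roc_area - 0.5)
    acc_e[s] <- loo_validate(sub["entropy_A8"], sub$label)$best$accuracy
    acc_l[s] <- loo_validate(sub["lf_hf"], sub$label)$best$accuracy
  }
  list(roc_entropy = mean(roc_e), roc_lfhf = mean(roc_l),
       acc_entropy = mean(acc_e), acc_lfhf = mean(acc_l))
}
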