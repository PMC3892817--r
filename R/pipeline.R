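# End-to-end orchestration: PERCLOS labelling, per-subject session
# simulation, window feature tables, selection, LOO classification, and a
# reproducible experiment directory with a manifest.

#' Label windows from PERCLOS values
#'
#' PERCLOS in \[0, 30%) marks an alert window and \[30%, 40%\] a drowsy one.
#' The 30% boundary is assigned to drowsy (fail-safe toward detection).
#' Values above 40% fall outside the protocol's calibrated range and are
#' labelled `out_of_range` with a warning; such windows are excluded from
#' training.
#'
#' @param perclos Numeric vector of fractions in \[0, 1\].
#' @return Character vector: `"alert"`, `"drowsy"` or `"out_of_range"`.
#' @export
label_from_perclos <- function(perclos) {
  if (any(!is.finite(perclos)) || any(perclos < 0 | perclos > 1))
    stop("PERCLOS values must lie in [0, 1]")
  out <- ifelse(perclos < 0.30, "alert",
                ifelse(perclos <= 0.40, "drowsy", "out_of_range"))
  if (any(out == "out_of_range"))
    warning(sum(out == "out_of_range"),
            " window(s) with PERCLOS > 40% excluded as out of range")
  out
}

#' Feature table for one session's IBI ground truth
#'
#' Resamples the session's interval series to a uniform tachogram, cuts it
#' into windows, and computes the 43 wavelet features plus band powers and
#' LF/HF per window.
#'
#' @param gt An `ibi_ground_truth` (or any `ibi_series`-like object with
#'   `interval_end_s`/`intervals_s`; for a ground truth the intervals are
#'   taken as simulated, anchored at the second beat of each pair).
#' @param window_length_s Window length in seconds.
#' @param resample_fs_hz Tachogram grid rate (Hz).
#' @param label Label attached to every window (defaults to the ground-truth
#'   label when present).
#' @return Data frame: `window_id`, `label`, 43 wavelet feature columns,
#'   `vlf`, `lf`, `hf`, `lf_hf`.
#' @export
session_features <- function(gt, window_length_s = 60, resample_fs_hz = 7,
                             label = gt$label) {
  ibi <- if (!is.null(gt$interval_end_s)) gt else
    list(interval_end_s = gt$beat_times_s[-1], intervals_s = gt$ibi_s)
  hrv <- resample_ibi(ibi, fs_hz = resample_fs_hz)
  wins <- cut_windows(hrv, length_s = window_length_s)
  if (!length(wins)) stop("session shorter than one analysis window")
  rows <- lapply(seq_along(wins), function(i) {
    w <- wins[[i]]
    wf <- wavelet_features(w)
    bp <- spectral_features(w)
    cbind(data.frame(window_id = i,
                     label = if (is.null(label)) NA_character_ else label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(wf)),
          data.frame(vlf = bp$vlf, lf = bp$lf, hf = bp$hf, lf_hf = bp$lf_hf))
  })
  do.call(rbind, rows)
}

#' Simulate one subject's alert and drowsy driving sessions
#'
#' Emulates the standard protocol: one 10-min alert session (stationary HRV
#' modulation) and one 10-min drowsy session (nonstationary: LF modulation
#' amplitude ramping 0.5x to 1.5x and mean IBI drifting upward across the
#' session), each divided into non-overlapping windows with features
#' extracted per window. Ten 1-min windows per session by default.
#'
#' @param seed Integer seed; the two sessions use derived seeds.
#' @param session_s Session duration in seconds.
#' @param window_length_s Analysis window length in seconds.
#' @param noise_sd Beat-level jitter (seconds) shared by both sessions.
#' @param subject_id Identifier added to the output.
#' @return Data frame as [session_features()], plus a `subject` column;
#'   alert windows first.
#' @export
simulate_subject <- function(seed, session_s = 605, window_length_s = 60,
                             noise_sd = 0.01, subject_id = "S1") {
  seed <- as.integer(seed)
  alert_cfg <- sim_config(duration_s = session_s, noise_sd = noise_sd,
                          seed = seed)
  drowsy_cfg <- sim_config(duration_s = session_s, noise_sd = noise_sd,
                           nonstationary = TRUE, seed = seed + 1000L)
  out <- rbind(
    session_features(simulate_ibi(alert_cfg), window_length_s = window_length_s),
    session_features(simulate_ibi(drowsy_cfg), window_length_s = window_length_s)
  )
  cbind(data.frame(subject = subject_id, stringsAsFactors = FALSE), out)
}

#' Experiment configuration
#'
#' Bundles every tunable of an end-to-end run so that a run is fully
#' reproducible from its manifest.
#'
#' @param n_subjects Number of simulated subjects.
#' @param seed Master seed; per-subject seeds are derived as
#'   `seed + 100 * subject_index`.
#' @param session_s Session duration (seconds).
#' @param window_length_s Window length: 60, 120 or 180 s.
#' @param features Character vector of feature columns handed to the
#'   classifier (default: the best wavelet feature, entropy of A8, paired
#'   with the LF/HF ratio).
#' @param grid SVM hyperparameter grid.
#' @param out_dir Output directory.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 4, seed = 1, session_s = 605,
                              window_length_s = 60,
                              features = c("entropy_A8", "lf_hf"),
                              grid = default_svm_grid(),
                              out_dir = tempfile("drowsyhrv_run_")) {
  stopifnot(window_length_s %in% c(60, 120, 180), n_subjects >= 1)
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 session_s = session_s, window_length_s = window_length_s,
                 features = features, grid = grid, out_dir = out_dir),
            class = "experiment_config")
}

# every tunable that a DESIGN DECISION fixes, with its active value
.design_parameters <- function(cfg) {
  list(
    peak_detector = list(domain = "differential", smooth_s = 0.1,
                         threshold_frac = 0.5, threshold_quantile = 0.75,
                         threshold_block_s = 5, refractory_s = 0.3,
                         refine_s = 0.15),
    interval_validity = list(range_s = c(0.3, 2.0), max_rel_jump = 0.75),
    resampling = list(fs_hz = 7, spline = "natural", knot_anchor = "second_beat"),
    psd = list(taper = "hann", welch_threshold_s = 120, welch_segment_s = 64,
               welch_overlap = 0.5),
    bands = hrv_bands(),
    wavelet = list(name = "sym3", level = 8, boundary = "symmetric",
                   entropy = "unnormalized -sum(c^2 log2 c^2)",
                   kurtosis = "non-excess", degenerate_kurtosis = 3,
                   degenerate_beta = 0),
    selection = list(rank_by = "abs(roc_area - 0.5)", acceptable = c(0.3, 0.7),
                     ttest = "pooled", mt_correction = "none"),
    svm = list(standardize = TRUE, tie_rule = "zero decision -> drowsy",
               grid_metric = "accuracy",
               tie_break = "linear kernel, then smaller C"),
    perclos = list(alert = c(0, 0.30), drowsy = c(0.30, 0.40),
                   boundary_0.30 = "drowsy", above_0.40 = "excluded"),
    generator = list(mean_ibi_s = 0.85, lf_amp = 0.03, hf_amp = 0.03,
                     vlf_amp = 0.01, lf_freq_hz = 0.1, hf_freq_hz = 0.3,
                     vlf_freq_hz = 0.02, noise_sd = 0.01,
                     drowsy_lf_ramp = c(0.5, 1.5), drowsy_ibi_drift_s = 0.15,
                     pulse_width_s = 0.35)
  )
}

#' Run a full simulated drowsiness-detection experiment
#'
#' Simulates the configured subjects, extracts the per-window feature table,
#' ranks features by ROC area, runs the independent t-tests, and evaluates
#' the selected feature pair per subject by leave-one-out SVM over the
#' hyperparameter grid. All results are written as CSV under
#' `cfg$out_dir`, together with a JSON manifest capturing the configuration,
#' all derived seeds, the package version and every fixed design parameter.
#' Runs with identical configuration and seed produce identical outputs.
#'
#' @param cfg An [experiment_config()].
#' @return Invisibly, a list with `features`, `ranking`, `ttests`,
#'   `loo` (per-subject grid results), `best` (per-subject best cells) and
#'   `out_dir`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  subj_seeds <- cfg$seed + 100L * seq_len(cfg$n_subjects)
  feats <- do.call(rbind, lapply(seq_len(cfg$n_subjects), function(i)
    simulate_subject(subj_seeds[i], session_s = cfg$session_s,
                     window_length_s = cfg$window_length_s,
                     subject_id = sprintf("S%d", i))))
  if (length(unique(feats$label)) < 2)
    stop("classification stage requires both classes: single class in feature table")

  feat_cols <- setdiff(names(feats), c("subject", "window_id", "label"))
  ranking <- rank_features(feats[feat_cols], feats$label)
  ttests <- feature_ttests(feats[feat_cols], feats$label)

  missing <- setdiff(cfg$features, names(feats))
  if (length(missing)) stop("unknown feature column(s): ",
                            paste(missing, collapse = ", "))
  loo <- list(); best <- list()
  for (s in unique(feats$subject)) {
    sub <- feats[feats$subject == s, , drop = FALSE]
    lv <- loo_validate(sub[cfg$features], sub$label, grid = cfg$grid)
    lv$results <- cbind(subject = s, lv$results)
    lv$best <- cbind(subject = s, lv$best)
    loo[[s]] <- lv$results
    best[[s]] <- lv$best
  }
  loo_all <- do.call(rbind, loo)
  best_all <- do.call(rbind, best)
  rownames(loo_all) <- rownames(best_all) <- NULL

  wr <- function(df, name) write.csv(df, file.path(cfg$out_dir, name),
                                     row.names = FALSE)
  wr(feats, "features.csv")
  wr(ranking, "roc_ranking.csv")
  wr(ttests, "ttests.csv")
  wr(loo_all, "loo_metrics.csv")
  wr(best_all, "loo_best.csv")
  manifest <- list(
    package = "drowsyhrv",
    version = as.character(packageVersion("drowsyhrv")),
    config = list(n_subjects = cfg$n_subjects, seed = cfg$seed,
                  subject_seeds = subj_seeds, session_s = cfg$session_s,
                  window_length_s = cfg$window_length_s,
                  features = cfg$features),
    grid = cfg$grid,
    design_parameters = .design_parameters(cfg)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(features = feats, ranking = ranking, ttests = ttests,
                 loo = loo_all, best = best_all, out_dir = cfg$out_dir))
}
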