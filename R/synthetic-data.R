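#' Simulation configuration for synthetic driving sessions
#'
#' Describes one simulated recording: the mean interbeat interval (IBI), the
#' amplitude and frequency of the sinusoidal VLF/LF/HF modulations riding on
#' it, optional beat-level jitter, a nonstationary "drowsy" schedule, and the
#' waveform-level nuisances (baseline wander, motion artifacts) used when the
#' IBI series is rendered into a PPG trace.
#'
#' The nonstationary schedule emulates a driver drifting into drowsiness over
#' the session: the LF modulation amplitude is ramped linearly between
#' `lf_ramp[1]` and `lf_ramp[2]` times `lf_amp`, and the mean IBI drifts by
#' `ibi_drift_s` seconds from start to end (heart rate slowing as vagal tone
#' rises). Stationary configurations represent the alert state.
#'
#' @param duration_s Session length in seconds.
#' @param mean_ibi_s Mean interbeat interval in seconds; must lie in
#'   \[0.3, 2\] (30--200 bpm).
#' @param vlf_amp,lf_amp,hf_amp Peak amplitude, in seconds, of the sinusoidal
#'   IBI modulation in the very-low, low and high frequency bands.
#' @param vlf_freq_hz,lf_freq_hz,hf_freq_hz Modulation frequencies (Hz);
#'   defaults 0.02, 0.1 and 0.3 sit at representative points of the VLF
#'   (0.003--0.04), LF (0.04--0.15) and HF (0.15--0.4) bands.
#' @param noise_sd Standard deviation (seconds) of white Gaussian beat-to-beat
#'   jitter added on top of the deterministic modulation; 0 disables it.
#' @param nonstationary Logical; apply the drowsy drift schedule?
#' @param lf_ramp Length-2 multiplier applied to `lf_amp` at session start and
#'   end when `nonstationary` is `TRUE`.
#' @param ibi_drift_s Linear drift of the mean IBI (seconds) across the
#'   session when `nonstationary` is `TRUE`.
#' @param artifact_rate Motion-artifact events per minute in the rendered PPG.
#' @param artifact_amp Artifact amplitude in pulse-amplitude units.
#' @param baseline_wander_amp Amplitude of the slow baseline oscillation in
#'   the rendered PPG, in pulse-amplitude units.
#' @param baseline_wander_freq_hz Frequency of the baseline wander (Hz).
#' @param pulse_width_s Total width of the pulse template (seconds).
#' @param seed Integer seed; a fixed seed makes every simulated array
#'   bit-identical across runs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_ibi()], [render_ppg()], [simulate_perclos()]
#' @export
#' @examples
#' cfg <- sim_config(duration_s = 120, seed = 1)
#' gt <- simulate_ibi(cfg)
#' head(gt$ibi_s)
sim_config <- function(duration_s = 600,
                       mean_ibi_s = 0.85,
                       vlf_amp = 0.01,
                       lf_amp = 0.03,
                       hf_amp = 0.03,
                       vlf_freq_hz = 0.02,
                       lf_freq_hz = 0.1,
                       hf_freq_hz = 0.3,
                       noise_sd = 0,
                       nonstationary = FALSE,
                       lf_ramp = c(0.5, 1.5),
                       ibi_drift_s = 0.15,
                       artifact_rate = 0,
                       artifact_amp = 2,
                       baseline_wander_amp = 0,
                       baseline_wander_freq_hz = 0.05,
                       pulse_width_s = 0.35,
                       seed = NULL) {
  stopifnot(is.numeric(duration_s), length(duration_s) == 1L, duration_s > 0)
  if (mean_ibi_s < 0.3 || mean_ibi_s > 2.0)
    stop("mean_ibi_s must lie in [0.3, 2.0] seconds")
  amps <- c(vlf_amp, lf_amp, hf_amp, artifact_amp, baseline_wander_amp)
  if (any(amps < 0)) stop("modulation and artifact amplitudes must be >= 0")
  if (length(lf_ramp) != 2L || any(lf_ramp < 0))
    stop("lf_ramp must be two non-negative multipliers")
  if (!is.null(seed)) seed <- as.integer(seed)
  cfg <- list(duration_s = duration_s, mean_ibi_s = mean_ibi_s,
              vlf_amp = vlf_amp, lf_amp = lf_amp, hf_amp = hf_amp,
              vlf_freq_hz = vlf_freq_hz, lf_freq_hz = lf_freq_hz,
              hf_freq_hz = hf_freq_hz, noise_sd = noise_sd,
              nonstationary = isTRUE(nonstationary), lf_ramp = lf_ramp,
              ibi_drift_s = ibi_drift_s, artifact_rate = artifact_rate,
              artifact_amp = artifact_amp,
              baseline_wander_amp = baseline_wander_amp,
              baseline_wander_freq_hz = baseline_wander_freq_hz,
              pulse_width_s = pulse_width_s, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

# Instantaneous IBI at time t under a config and fixed modulation phases.
.ibi_at <- function(t, cfg, phases) {
  frac <- if (cfg$duration_s > 0) pmin(t / cfg$duration_s, 1) else 0
  lf_mult <- 1
  m <- cfg$mean_ibi_s
  if (cfg$nonstationary) {
    lf_mult <- cfg$lf_ramp[1] + (cfg$lf_ramp[2] - cfg$lf_ramp[1]) * frac
    m <- m + cfg$ibi_drift_s * frac
  }
  m +
    cfg$vlf_amp * sin(2 * pi * cfg$vlf_freq_hz * t + phases[1]) +
    cfg$lf_amp * lf_mult * sin(2 * pi * cfg$lf_freq_hz * t + phases[2]) +
    cfg$hf_amp * sin(2 * pi * cfg$hf_freq_hz * t + phases[3])
}

#' Simulate a ground-truthed interbeat-interval series
#'
#' Generates beat times by integrating an instantaneous IBI signal: the next
#' beat falls one current-IBI after the previous one, where the current IBI is
#' the configured mean plus sinusoidal VLF/LF/HF modulations (and optional
#' white jitter). The true LF/HF power ratio implied by the configuration,
#' `(lf_amp / hf_amp)^2`, is recorded alongside so spectral estimators can be
#' validated against it.
#'
#' Modulation phases are drawn uniformly when a seed is set (and are zero
#' otherwise), so repeated windows from different seeds differ while a fixed
#' seed reproduces the series exactly.
#'
#' @param config A [sim_config()].
#' @return An object of class `ibi_ground_truth`: a list with `beat_times_s`
#'   (strictly increasing), `ibi_s` (`diff(beat_times_s)`), `true_lf_hf`,
#'   `label` (`"drowsy"` if the nonstationary schedule is active, else
#'   `"alert"`) and the generating `config`.
#' @export
simulate_ibi <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  phases <- c(0, 0, 0)
  jitter_fun <- function() 0
  if (!is.null(config$seed) || config$noise_sd > 0) {
    if (!is.null(config$seed)) set.seed(config$seed)
    phases <- runif(3, 0, 2 * pi)
    if (config$noise_sd > 0)
      jitter_fun <- function() rnorm(1, 0, config$noise_sd)
  }
  # generous upper bound on the number of beats
  n_max <- ceiling(config$duration_s / max(config$mean_ibi_s - config$vlf_amp -
                                             config$lf_amp * max(config$lf_ramp) -
                                             config$hf_amp, 0.25)) + 2L
  times <- numeric(n_max)
  # first beat at 0.5 s so the rendered record starts shortly before the
  # first pulse and no pulse is truncated at the record edge
  t <- 0.5
  k <- 1L
  while (t <= config$duration_s) {
    times[k] <- t
    ibi <- .ibi_at(t, config, phases) + jitter_fun()
    # reject at 0.1 s rather than 0: near a zero crossing the beat-time
    # iteration would otherwise stall asymptotically instead of failing
    if (ibi <= 0.1)
      stop("modulation amplitudes too large: interbeat interval fell to ",
           signif(ibi, 3), " s at t = ", signif(t, 4), " s")
    t <- t + ibi
    k <- k + 1L
  }
  beat_times <- times[seq_len(k - 1L)]
  lf_eff <- config$lf_amp *
    (if (config$nonstationary) mean(config$lf_ramp) else 1)
  true_lf_hf <- if (config$hf_amp > 0) (lf_eff / config$hf_amp)^2 else NA_real_
  out <- list(beat_times_s = beat_times,
              ibi_s = diff(beat_times),
              true_lf_hf = true_lf_hf,
              label = if (config$nonstationary) "drowsy" else "alert",
              config = config)
  class(out) <- "ibi_ground_truth"
  out
}

# Asymmetric raised-cosine pulse: fast systolic rise, slower decay, unit peak
# centred at offset 0 so the waveform maximum lands on the beat time.
.pulse_template <- function(tau, width_s) {
  rise <- width_s * 2 / 7   # 0.1 s of a 0.35 s pulse
  fall <- width_s * 5 / 7
  y <- numeric(length(tau))
  up <- tau >= -rise & tau < 0
  dn <- tau >= 0 & tau <= fall
  y[up] <- 0.5 * (1 + cos(pi * tau[up] / rise))
  y[dn] <- 0.5 * (1 + cos(pi * tau[dn] / fall))
  y
}

#' Render a PPG waveform from simulated beats
#'
#' Places one asymmetric raised-cosine pulse per beat (peak exactly at the
#' beat time), then adds slow sinusoidal baseline wander and sparse motion
#' artifacts (steps and short ramps, the disturbances a first-order
#' differential suppresses best), as configured.
#'
#' @param gt An `ibi_ground_truth` from [simulate_ibi()], or any list with a
#'   `beat_times_s` field.
#' @param fs_hz Sampling rate; must be at least 20 Hz (default 40, the rate of
#'   a typical steering-wheel PPG node).
#' @param config A [sim_config()]; supplies wander/artifact settings. Defaults
#'   to the config stored in `gt`.
#' @return A [ppg_record()] whose `beat_idx` attribute holds the true beat
#'   sample indices (1-based) and `artifact_times_s` the injected artifact
#'   onsets.
#' @export
render_ppg <- function(gt, fs_hz = 40, config = gt$config) {
  stopifnot(fs_hz >= 20)
  if (is.null(config)) config <- sim_config()
  duration <- config$duration_s
  n <- floor(duration * fs_hz) + 1L
  tt <- (seq_len(n) - 1L) / fs_hz
  x <- numeric(n)
  beats <- gt$beat_times_s
  half <- config$pulse_width_s
  for (b in beats) {
    lo <- max(1L, floor((b - half) * fs_hz) + 1L)
    hi <- min(n, ceiling((b + half) * fs_hz) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    x[idx] <- x[idx] + .pulse_template(tt[idx] - b, config$pulse_width_s)
  }
  if (config$baseline_wander_amp > 0)
    x <- x + config$baseline_wander_amp *
      sin(2 * pi * config$baseline_wander_freq_hz * tt)
  artifact_times <- numeric(0)
  n_art <- round(config$artifact_rate * duration / 60)
  if (n_art > 0) {
    if (!is.null(config$seed)) set.seed(config$seed + 1L)
    artifact_times <- sort(runif(n_art, 0, duration))
    for (j in seq_len(n_art)) {
      t0 <- artifact_times[j]
      amp <- config$artifact_amp * runif(1, 0.5, 1.5) * sample(c(-1, 1), 1)
      if (j %% 2 == 1) {                       # step held to end of record
        x[tt >= t0] <- x[tt >= t0] + amp
      } else {                                 # 2-s ramp, then held
        ramp <- pmin(pmax((tt - t0) / 2, 0), 1)
        x <- x + amp * ramp
      }
    }
  }
  rec <- ppg_record(x, fs_hz = fs_hz, t0_s = 0)
  attr(rec, "beat_idx") <- round(beats * fs_hz) + 1L
  attr(rec, "artifact_times_s") <- artifact_times
  rec
}

#' Simulate PERCLOS values for labelled windows
#'
#' PERCLOS (percentage of eyelid closure over the pupil over time) is the
#' ground-truth drowsiness measure: values in \[0, 30%) mark alert driving and
#' \[30%, 40%\] drowsy driving. Values are drawn uniformly within the band of
#' the requested state.
#'
#' @param label `"alert"` or `"drowsy"`.
#' @param n_windows Number of 1-min windows (>= 0; 0 gives an empty vector).
#' @param seed Optional integer seed.
#' @return Numeric vector of PERCLOS fractions in \[0, 1\].
#' @export
simulate_perclos <- function(label = c("alert", "drowsy"), n_windows, seed = NULL) {
  label <- match.arg(label)
  stopifnot(n_windows >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (n_windows == 0) return(numeric(0))
  if (label == "alert") runif(n_windows, 0, 0.30 - 1e-9)
  else runif(n_windows, 0.30, 0.40)
}

#' Write a PPG record as a two-column CSV
#'
#' Columns are `time_s` and `amplitude`; header comment lines record the
#' sampling rate and, when available, the simulation seed.
#'
#' @param rec A [ppg_record()].
#' @param path Output file path.
#' @param seed Optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_ppg_csv <- function(rec, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz: %g", rec$fs_hz), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  tt <- rec$t0_s + (seq_along(rec$samples) - 1L) / rec$fs_hz
  writeLines("time_s,amplitude", con)
  writeLines(sprintf("%.6f,%.8g", tt, rec$samples), con)
  invisible(path)
}

#' Read a PPG record from CSV
#'
#' Accepts the two-column `time_s,amplitude` layout written by
#' [write_ppg_csv()] (comment lines starting with `#` are skipped); the
#' sampling rate is taken from the header when present, else inferred from the
#' median time step.
#'
#' @param path CSV file path.
#' @return A [ppg_record()].
#' @export
read_ppg_csv <- function(path) {
  header <- readLines(path, n = 10)
  fs <- NA_real_
  m <- grep("^# fs_hz:", header, value = TRUE)
  if (length(m)) fs <- as.numeric(sub("^# fs_hz:\\s*", "", m[1]))
  df <- read.csv(path, comment.char = "#")
  if (!all(c("time_s", "amplitude") %in% names(df)))
    stop("expected columns time_s and amplitude")
  if (is.na(fs)) fs <- 1 / stats::median(diff(df$time_s))
  ppg_record(df$amplitude, fs_hz = fs, t0_s = df$time_s[1])
}

#' Write simulated ground truth (beat times and intervals) as CSV
#'
#' @param gt An `ibi_ground_truth`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(gt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(gt$config$seed))
    writeLines(sprintf("# seed: %d", gt$config$seed), con)
  writeLines(sprintf("# label: %s", gt$label), con)
  writeLines("beat_time_s,ibi_s", con)
  ibi <- c(NA, gt$ibi_s)
  writeLines(sprintf("%.9f,%s", gt$beat_times_s,
                     ifelse(is.na(ibi), "", sprintf("%.9f", ibi))), con)
  invisible(path)
}
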