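#' PPG record container
#'
#' A uniformly sampled photoplethysmogram: amplitude samples plus sampling
#' rate and start time.
#'
#' @param samples Numeric amplitude vector (length >= 2 for any processing).
#' @param fs_hz Sampling rate in Hz (> 0).
#' @param t0_s Start time in seconds.
#' @return An object of class `ppg_record`.
#' @export
ppg_record <- function(samples, fs_hz, t0_s = 0) {
  stopifnot(is.numeric(samples), is.numeric(fs_hz), fs_hz > 0)
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz, t0_s = t0_s),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs_hz, length(x$samples) / x$fs_hz))
  invisible(x)
}

#' First-order differential of a PPG record
#'
#' Computes `v(x) = (y(x) - y(x-1)) / dt` with `dt = 1/fs`. This is the
#' artifact-suppression step of the pipeline: a constant offset (e.g. a
#' pressure step from a grip change on the steering wheel) maps to a single
#' spike, and a linear drift maps to a constant, so neither disturbs
#' peak-to-peak timing.
#'
#' @param rec A [ppg_record()] with at least 2 samples.
#' @return An object of class `diff_series`: list with `values` (length one
#'   less than the input), `fs_hz` and `t0_s`.
#' @export
differentiate <- function(rec) {
  stopifnot(inherits(rec, "ppg_record"))
  if (length(rec$samples) < 2) stop("signal too short: need at least 2 samples")
  structure(list(values = diff(rec$samples) * rec$fs_hz,
                 fs_hz = rec$fs_hz, t0_s = rec$t0_s + 1 / rec$fs_hz),
            class = "diff_series")
}

# moving average smoother, centred, width clamped to an odd number of samples
.smooth_ma <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2 == 0) width <- width + 1L
  if (width == 1L) return(x)
  k <- rep(1 / width, width)
  y <- stats::filter(x, k, sides = 2)
  y[is.na(y)] <- 0
  as.numeric(y)
}

#' Detect pulse peaks in a PPG record
#'
#' Detection runs in the differential domain by default: the record is
#' differenced, smoothed with a short moving average, and candidate beats are
#' local maxima exceeding an adaptive threshold (half of the 75th percentile
#' of positive smoothed values, computed per 5-s block). A refractory period
#' suppresses double detections, and each beat is then refined to the nearest
#' raw-signal local maximum so reported times match waveform peaks.
#'
#' @param rec A [ppg_record()] of duration >= 2 s.
#' @param domain `"differential"` (default) or `"raw"`: the signal the peak
#'   search runs on. Refinement to the raw maximum happens in both cases.
#' @param smooth_s Moving-average width in seconds.
#' @param refractory_s Minimum peak spacing in seconds (0.3 s caps heart rate
#'   at 200 bpm).
#' @param threshold_frac Fraction of the blockwise 75th percentile used as the
#'   detection threshold.
#' @param refine_s Half-width of the raw-maximum refinement search, seconds.
#' @return Integer vector of strictly increasing 1-based beat sample indices,
#'   with attribute `fs_hz`. Empty (with a warning) if nothing crosses the
#'   threshold; downstream stages must reject such windows.
#' @export
detect_peaks <- function(rec, domain = c("differential", "raw"),
                         smooth_s = 0.1, refractory_s = 0.3,
                         threshold_frac = 0.5, refine_s = 0.15) {
  stopifnot(inherits(rec, "ppg_record"))
  domain <- match.arg(domain)
  fs <- rec$fs_hz
  if (length(rec$samples) / fs < 2)
    stop("signal too short: need at least 2 s for peak detection")
  work <- if (domain == "differential") differentiate(rec)$values else rec$samples
  offset <- if (domain == "differential") 1L else 0L
  s <- .smooth_ma(work, round(smooth_s * fs))
  n <- length(s)

  # adaptive threshold: per non-overlapping 5-s block, half the 75th
  # percentile of the positive part (floor guards flat blocks)
  block <- max(1L, as.integer(5 * fs))
  thr <- numeric(n)
  gmax <- max(s, 0)
  for (b0 in seq(1L, n, by = block)) {
    idx <- b0:min(n, b0 + block - 1L)
    pos <- s[idx][s[idx] > 0]
    q <- if (length(pos)) quantile(pos, 0.75, names = FALSE) else Inf
    thr[idx] <- max(threshold_frac * q, 1e-3 * gmax)
  }

  cand <- which(s > thr &
                  s > c(-Inf, s[-n]) &
                  s >= c(s[-1], -Inf))
  if (!length(cand)) {
    warning("no pulse peaks detected")
    return(structure(integer(0), fs_hz = fs))
  }

  # refractory: sequential scan, keep the larger of two close candidates
  refr <- refractory_s * fs
  kept <- cand[1]
  for (c1 in cand[-1]) {
    last <- kept[length(kept)]
    if (c1 - last >= refr) kept <- c(kept, c1)
    else if (s[c1] > s[last]) kept[length(kept)] <- c1
  }

  # refine to the raw-signal local maximum near each detection
  half <- max(1L, as.integer(round(refine_s * fs)))
  raw <- rec$samples
  peaks <- vapply(kept + offset, function(i) {
    lo <- max(1L, i - half)
    hi <- min(length(raw), i + half)
    lo + which.max(raw[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refinement can merge neighbours; re-apply refractory on raw indices
  if (length(peaks) > 1) {
    out <- peaks[1]
    for (p in peaks[-1]) if (p - out[length(out)] >= refr) out <- c(out, p)
    peaks <- out
  }
  structure(as.integer(peaks), fs_hz = fs)
}

#' Peak-to-peak intervals from beat indices
#'
#' Converts detected beat sample indices to beat times and interbeat
#' intervals, then applies a physiological validity filter: intervals outside
#' (0.3, 2.0) s, or differing from the preceding valid interval by more than
#' 75%, are dropped (ectopic or missed beats must not corrupt the spline
#' resampling). Each surviving interval stays anchored at the time of its
#' second beat -- the moment the interval becomes known.
#'
#' @param peaks Integer vector of 1-based beat sample indices (>= 2), e.g.
#'   from [detect_peaks()].
#' @param fs_hz Sampling rate of the source record; defaults to the `fs_hz`
#'   attribute of `peaks` when present.
#' @param t0_s Start time of the source record.
#' @return An object of class `ibi_series`: list with `beat_times_s` (all
#'   beats), `intervals_s` and `interval_end_s` (valid intervals and their
#'   anchor times), `n_dropped`, and `source_fs_hz`.
#' @export
to_ibi <- function(peaks, fs_hz = attr(peaks, "fs_hz"), t0_s = 0) {
  if (is.null(fs_hz)) stop("fs_hz must be supplied")
  if (length(peaks) < 2) stop("cannot form intervals: need at least 2 peaks")
  if (any(diff(peaks) <= 0)) stop("peak indices must be strictly increasing")
  times <- t0_s + (as.numeric(peaks) - 1) / fs_hz
  iv <- diff(times)
  ends <- times[-1]
  keep <- logical(length(iv))
  prev <- NA_real_
  for (i in seq_along(iv)) {
    ok <- iv[i] > 0.3 && iv[i] < 2.0
    if (ok && !is.na(prev) && abs(iv[i] - prev) / prev > 0.75) ok <- FALSE
    keep[i] <- ok
    if (ok) prev <- iv[i]
  }
  structure(list(beat_times_s = times,
                 intervals_s = iv[keep],
                 interval_end_s = ends[keep],
                 n_dropped = sum(!keep),
                 source_fs_hz = fs_hz),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d beats, %d valid intervals (%d dropped), mean %.3f s\n",
              length(x$beat_times_s), length(x$intervals_s), x$n_dropped,
              mean(x$intervals_s)))
  invisible(x)
}

#' Extract a beat sequence from a PPG record
#'
#' Convenience wrapper chaining [detect_peaks()] and [to_ibi()].
#'
#' @inheritParams detect_peaks
#' @param ... Passed to [detect_peaks()].
#' @return An `ibi_series`.
#' @export
extract_ibi <- function(rec, ...) {
  peaks <- detect_peaks(rec, ...)
  if (length(peaks) < 2) stop("cannot form intervals: fewer than 2 beats detected")
  to_ibi(peaks, fs_hz = rec$fs_hz, t0_s = rec$t0_s)
}

#' Write beat times and intervals to CSV files
#'
#' @param ibi An `ibi_series`.
#' @param beats_path Path for the beat-time CSV (single column `beat_time_s`).
#' @param intervals_path Optional path for a one-value-per-line interval list
#'   (seconds).
#' @return `beats_path`, invisibly.
#' @export
write_ibi_csv <- function(ibi, beats_path, intervals_path = NULL) {
  write.csv(data.frame(beat_time_s = ibi$beat_times_s), beats_path,
            row.names = FALSE)
  if (!is.null(intervals_path))
    writeLines(sprintf("%.9f", ibi$intervals_s), intervals_path)
  invisible(beats_path)
}
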