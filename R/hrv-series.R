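#' Evenly resampled HRV series
#'
#' Internal constructor for the uniformly sampled tachogram used by both
#' feature extractors.
#'
#' @param values Interval amplitudes in seconds.
#' @param fs_hz Sampling rate of the grid (Hz).
#' @param start_s Time of the first grid point (seconds).
#' @param window_length_s Nominal window length, if this series is a cut
#'   window.
#' @return An object of class `hrv_series`.
#' @export
hrv_series <- function(values, fs_hz, start_s = 0, window_length_s = NULL) {
  stopifnot(is.numeric(values), fs_hz > 0)
  structure(list(values = as.numeric(values), fs_hz = fs_hz,
                 start_s = start_s, window_length_s = window_length_s),
            class = "hrv_series")
}

#' @export
print.hrv_series <- function(x, ...) {
  cat(sprintf("<hrv_series> %d samples @ %g Hz, start %.2f s\n",
              length(x$values), x$fs_hz, x$start_s))
  invisible(x)
}

#' Resample an interbeat-interval series onto a uniform grid
#'
#' Fits an interpolating cubic spline through the (anchor time, interval)
#' knots of the IBI series and evaluates it on a uniform grid at `fs_hz`
#' (7 Hz by default) running from the first to the last knot. Interpolation
#' only -- the spline passes through every knot exactly and is never evaluated
#' beyond the knot range.
#'
#' @param ibi An `ibi_series` (see [to_ibi()]) with at least 4 valid
#'   intervals, or any list with `interval_end_s` and `intervals_s` fields.
#' @param fs_hz Grid rate in Hz; 7 Hz upsamples the tachogram enough for FFT
#'   analysis of the 0--0.4 Hz HRV bands.
#' @param method Spline boundary handling passed to [stats::splinefun()]:
#'   `"natural"` (default, zero second derivative at the ends) or `"fmm"`.
#' @return An [hrv_series()].
#' @export
resample_ibi <- function(ibi, fs_hz = 7, method = c("natural", "fmm")) {
  method <- match.arg(method)
  knots_t <- ibi$interval_end_s
  knots_v <- ibi$intervals_s
  if (length(knots_v) < 4)
    stop("insufficient beats for spline: need at least 4 valid intervals")
  f <- splinefun(knots_t, knots_v, method = method)
  grid <- seq(knots_t[1], knots_t[length(knots_t)], by = 1 / fs_hz)
  hrv_series(f(grid), fs_hz = fs_hz, start_s = knots_t[1])
}

#' Cut an HRV series into fixed-length analysis windows
#'
#' Splits the resampled series into consecutive windows of exactly
#' `length_s` seconds (1, 2 or 3 min in the standard protocol). Windows do
#' not overlap by default; a 10-min session therefore yields ten 1-min
#' windows.
#'
#' @param hrv An [hrv_series()].
#' @param length_s Window length in seconds (typically 60, 120 or 180).
#' @param hop_s Hop between window starts; defaults to `length_s`
#'   (non-overlapping).
#' @return A list of [hrv_series()] windows, each tagged with its
#'   `window_length_s` and absolute `start_s`. Empty (with a warning) if the
#'   record is shorter than one window.
#' @export
cut_windows <- function(hrv, length_s = 60, hop_s = length_s) {
  stopifnot(inherits(hrv, "hrv_series"), length_s > 0, hop_s > 0)
  n_win <- as.integer(round(length_s * hrv$fs_hz))
  hop <- as.integer(round(hop_s * hrv$fs_hz))
  n <- length(hrv$values)
  if (n < n_win) {
    warning("record shorter than one window; returning no windows")
    return(list())
  }
  starts <- seq(1L, n - n_win + 1L, by = hop)
  lapply(starts, function(s0) {
    hrv_series(hrv$values[s0:(s0 + n_win - 1L)], fs_hz = hrv$fs_hz,
               start_s = hrv$start_s + (s0 - 1L) / hrv$fs_hz,
               window_length_s = length_s)
  })
}

#' Write an HRV window to CSV
#'
#' Two columns (`t_s`, `ibi_s`) with a header comment recording the grid rate
#' and window id.
#'
#' @param hrv An [hrv_series()].
#' @param path Output path.
#' @param window_id Identifier recorded in the header.
#' @return `path`, invisibly.
#' @export
write_hrv_csv <- function(hrv, path, window_id = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz: %g", hrv$fs_hz), con)
  if (!is.na(window_id)) writeLines(sprintf("# window_id: %s", window_id), con)
  tt <- hrv$start_s + (seq_along(hrv$values) - 1L) / hrv$fs_hz
  writeLines("t_s,ibi_s", con)
  writeLines(sprintf("%.6f,%.9f", tt, hrv$values), con)
  invisible(path)
}
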