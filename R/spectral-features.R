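#' HRV frequency bands
#'
#' The standard short-term HRV band edges: very-low frequency 0.003--0.04 Hz,
#' low frequency 0.04--0.15 Hz, high frequency 0.15--0.4 Hz.
#'
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
hrv_bands <- function() {
  list(vlf = c(0.003, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.4))
}

# Hann-tapered one-sided periodogram, scaled so that sum(P) * df equals the
# variance of the mean-removed segment (up to taper leakage).
.periodogram <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  xw <- x * w
  X <- fft(xw)
  nf <- floor(n / 2) + 1L
  p <- (Mod(X[seq_len(nf)])^2) / (fs * sum(w^2))
  # one-sided: double everything except DC (and Nyquist when n is even)
  scale2 <- rep(2, nf)
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / n, density = p * scale2)
}

#' Power spectral density of an HRV window
#'
#' FFT-based one-sided PSD of the mean-removed window. Windows shorter than
#' two minutes use a single Hann-tapered periodogram; longer windows use
#' Welch averaging (64-s segments, 50% overlap) to trade frequency resolution
#' for variance. Satisfies Parseval: the integral of the density over
#' frequency matches the variance of the mean-removed window.
#'
#' @param hrv An [hrv_series()] of at least 60 s.
#' @param method `"auto"` (periodogram below 120 s, Welch at or above),
#'   `"periodogram"`, or `"welch"`.
#' @param seg_s Welch segment length in seconds.
#' @return List with `freq` (Hz, from 0 to fs/2) and `density`
#'   (s^2/Hz).
#' @export
hrv_psd <- function(hrv, method = c("auto", "periodogram", "welch"),
                    seg_s = 64) {
  stopifnot(inherits(hrv, "hrv_series"))
  method <- match.arg(method)
  n <- length(hrv$values)
  fs <- hrv$fs_hz
  dur <- n / fs
  if (dur < 60) stop("window too short for HRV spectral analysis: need >= 60 s")
  if (method == "auto") method <- if (dur < 120) "periodogram" else "welch"
  x <- hrv$values
  if (method == "periodogram") return(.periodogram(x, fs))
  nseg <- min(as.integer(round(seg_s * fs)), n)
  hop <- max(1L, nseg %/% 2L)
  starts <- seq(1L, n - nseg + 1L, by = hop)
  acc <- NULL
  for (s0 in starts) {
    p <- .periodogram(x[s0:(s0 + nseg - 1L)], fs)
    acc <- if (is.null(acc)) p$density else acc + p$density
  }
  list(freq = p$freq, density = acc / length(starts))
}

# trapezoidal integral of density over the closed band [lo, hi], with linear
# interpolation at the exact band edges
.band_integral <- function(freq, density, lo, hi) {
  lo <- max(lo, freq[1]); hi <- min(hi, freq[length(freq)])
  if (hi <= lo) return(0)
  inside <- freq > lo & freq < hi
  f <- c(lo, freq[inside], hi)
  d <- c(approx(freq, density, xout = lo)$y, density[inside],
         approx(freq, density, xout = hi)$y)
  sum(diff(f) * (head2(d) + d[-1]) / 2)
}

head2 <- function(x) x[-length(x)]

#' Band powers and the LF/HF ratio
#'
#' Integrates a PSD over the VLF, LF and HF bands (trapezoid rule on the
#' closed intervals) and forms the LF/HF sympathovagal balance index. When
#' the HF power is zero the ratio is undefined and returned as `NA` (never
#' infinity); callers must exclude such windows.
#'
#' @param freq,density A PSD as returned by [hrv_psd()].
#' @param edges Band edges, as from [hrv_bands()].
#' @return An object of class `band_powers`: list with `vlf`, `lf`, `hf`
#'   (s^2), `lf_hf` (dimensionless or `NA`), and `band_edges`.
#' @export
band_powers <- function(freq, density, edges = hrv_bands()) {
  stopifnot(length(freq) == length(density), all(density >= -1e-15))
  p <- lapply(edges, function(e) .band_integral(freq, density, e[1], e[2]))
  lf_hf <- if (p$hf > 0) p$lf / p$hf else NA_real_
  structure(list(vlf = p$vlf, lf = p$lf, hf = p$hf, lf_hf = lf_hf,
                 band_edges = edges),
            class = "band_powers")
}

#' @export
print.band_powers <- function(x, ...) {
  cat(sprintf("<band_powers> VLF %.3g  LF %.3g  HF %.3g  LF/HF %s\n",
              x$vlf, x$lf, x$hf,
              if (is.na(x$lf_hf)) "undefined" else sprintf("%.3g", x$lf_hf)))
  invisible(x)
}

#' Spectral features of an HRV window
#'
#' Convenience wrapper: PSD then band powers.
#'
#' @param hrv An [hrv_series()].
#' @param ... Passed to [hrv_psd()].
#' @return A [band_powers()] object.
#' @export
spectral_features <- function(hrv, ...) {
  p <- hrv_psd(hrv, ...)
  band_powers(p$freq, p$density)
}
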