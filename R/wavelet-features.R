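# Wavelet-domain HRV features: per-level Shannon entropy, mean, variance and
# kurtosis for D1..D8 and A8 (36 values) plus the multiscale spectral slope
# beta for the 7 adjacent detail-level pairs -- 43 features per window.

#' Wavelet Shannon entropy of a coefficient set
#'
#' The unnormalized energy-weighted entropy `E = -sum(c^2 * log2(c^2))`, with
#' the `0 * log(0) = 0` convention, reported in bits. Unnormalized on
#' purpose: coefficient energies of a realistic tachogram window put this
#' statistic on the order of 10^4 bit, whereas a probability-normalized
#' entropy would be bounded by `log2` of the coefficient count. Note the sum
#' is signed -- coefficients with `c^2 > 1` contribute negatively.
#'
#' @param coeffs Numeric coefficient vector.
#' @return Entropy in bits (0 for an all-zero set).
#' @export
wavelet_entropy <- function(coeffs) {
  e <- coeffs^2
  nz <- e > 0
  -sum(e[nz] * log2(e[nz]))
}

#' Sample moments of a coefficient set
#'
#' Mean, unbiased sample variance, and kurtosis as the standardized fourth
#' moment (non-excess: a large Gaussian sample gives about 3). Kurtosis is
#' `NA` for a zero-variance (degenerate) set; [wavelet_features()] imputes
#' the Gaussian reference value 3 in that case.
#'
#' @param coeffs Numeric vector; kurtosis needs at least 4 values.
#' @return Named list `mean`, `variance`, `kurtosis`.
#' @export
coef_moments <- function(coeffs) {
  m <- mean(coeffs)
  v <- if (length(coeffs) > 1) var(coeffs) else 0
  m2 <- mean((coeffs - m)^2)
  k <- if (m2 > .deg_var) mean((coeffs - m)^4) / m2^2 else NA_real_
  list(mean = m, variance = v, kurtosis = k)
}

# variance floor below which a level counts as degenerate: coefficient
# spread at this scale (1e-9 s) is numerical dust, far below any
# physiological variability
.deg_var <- 1e-18

#' Multiscale spectral slope between adjacent detail levels
#'
#' The local slope of log2 coefficient variance across one dyadic scale step,
#' `beta = log2(var(D[j+1])) - log2(var(D[j]))` -- a surrogate for the
#' spectral exponent of the signal in the octave spanned by the pair. Being a
#' variance *ratio* on a log scale, beta is invariant to rescaling the input
#' window.
#'
#' @param decomp A [wavelet_decompose()] result.
#' @param pair Integer pair `c(j + 1, j)` of adjacent detail levels, coarser
#'   first.
#' @return Dimensionless slope; `NA` when either level has zero variance
#'   ([wavelet_features()] imputes 0).
#' @export
multiscale_beta <- function(decomp, pair) {
  stopifnot(inherits(decomp, "wavelet_decomposition"), length(pair) == 2)
  if (any(pair < 1 | pair > decomp$level) || pair[1] - pair[2] != 1)
    stop("pair must be adjacent detail levels c(j + 1, j) within the decomposition")
  v1 <- var(decomp$details[[pair[1]]])
  v0 <- var(decomp$details[[pair[2]]])
  if (v1 <= .deg_var || v0 <= .deg_var) return(NA_real_)
  log2(v1) - log2(v0)
}

#' The 43-value wavelet feature vector of an HRV window
#'
#' Decomposes the window (Symlet-3, 8 levels by default) and extracts, for
#' each of D1..D8 and A8: Shannon entropy, mean, variance and kurtosis (36
#' values), plus the multiscale slope beta for the 7 adjacent detail pairs
#' D8D7 .. D2D1. Degenerate levels (zero variance) get kurtosis imputed as 3
#' (Gaussian reference) and beta as 0, with a warning -- on realistic data a
#' degenerate level signals an upstream failure.
#'
#' @param hrv An [hrv_series()] or numeric vector of at least `2^level`
#'   samples (a 1-min window at 7 Hz qualifies for the default depth 8).
#' @param wavelet,level,boundary Passed to [wavelet_decompose()].
#' @return Named numeric vector of exactly 43 finite features:
#'   `entropy_D1` .. `kurtosis_A8`, then `beta_D8D7` .. `beta_D2D1`.
#' @export
wavelet_features <- function(hrv, wavelet = "sym3", level = 8,
                             boundary = "symmetric") {
  decomp <- wavelet_decompose(hrv, wavelet = wavelet, level = level,
                              boundary = boundary)
  sets <- c(decomp$details, list(decomp$approximation))
  names(sets) <- c(names(decomp$details), paste0("A", level))
  out <- numeric(0)
  degenerate <- character(0)
  for (nm in names(sets)) {
    cc <- sets[[nm]]
    mo <- coef_moments(cc)
    k <- mo$kurtosis
    if (is.na(k)) { k <- 3; degenerate <- c(degenerate, nm) }
    v <- c(wavelet_entropy(cc), mo$mean, mo$variance, k)
    names(v) <- paste0(c("entropy_", "mean_", "variance_", "kurtosis_"), nm)
    out <- c(out, v)
  }
  for (j in seq(level, 2)) {
    b <- multiscale_beta(decomp, c(j, j - 1))
    if (is.na(b)) { b <- 0; degenerate <- c(degenerate, paste0("beta D", j, "D", j - 1)) }
    names(b) <- sprintf("beta_D%dD%d", j, j - 1)
    out <- c(out, b)
  }
  if (length(degenerate))
    warning("degenerate (zero-variance) wavelet levels, imputed defaults: ",
            paste(unique(degenerate), collapse = ", "))
  out
}
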