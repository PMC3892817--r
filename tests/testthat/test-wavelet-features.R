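# Reference coefficients below were computed independently with an external
# wavelet library (sym3, symmetric boundary) and frozen.
ref_x <- c(1.76405235, 0.40015721, 0.97873798, 2.2408932, 1.86755799,
           -0.97727788, 0.95008842, -0.15135721, -0.10321885, 0.4105985,
           0.14404357)
ref_cA <- c(1.34444451, 2.30905547, 0.86329362, 3.03803767, 0.31336652,
            0.0838011, 0.30504742, 0.41330753)
ref_cD <- c(0.5875677, -0.21311468, 0.76568244, 1.24019964, -0.2962598,
            -0.08604491, 0.31140249, -0.42878119)

test_that("single-level sym3 analysis matches the frozen external reference", {
  d <- wavelet_decompose(ref_x, wavelet = "sym3", level = 1)
  expect_equal(d$approximation, ref_cA, tolerance = 1e-7)
  expect_equal(d$details$D1, ref_cD, tolerance = 1e-7)
})

test_that("an eight-level decomposition returns nine coefficient sets and reconstructs", {
  set.seed(2)
  x <- rnorm(420, 0.85, 0.05)
  d <- wavelet_decompose(x, level = 8)
  expect_length(d$details, 8)
  expect_named(d$details, paste0("D", 1:8))
  expect_true(length(d$approximation) >= 4)
  rec <- wavelet_reconstruct(d)
  expect_lt(max(abs(rec - x)) / max(abs(x)), 1e-8)
})

test_that("too-short inputs are rejected with the required minimum", {
  expect_error(wavelet_decompose(rnorm(200), level = 8), ">= 256")
})

test_that("the periodized transform is orthogonal: energy is conserved", {
  set.seed(9)
  x <- rnorm(512)
  d <- wavelet_decompose(x, level = 8, boundary = "periodic")
  energy <- sum(vapply(d$details, function(cc) sum(cc^2), 0)) +
    sum(d$approximation^2)
  expect_equal(energy, sum(x^2), tolerance = 1e-6)
  expect_lt(max(abs(wavelet_reconstruct(d) - x)), 1e-9)
})

test_that("band-limited noise in 0.11-0.22 Hz lands in detail level 5 at 7 Hz", {
  set.seed(13)
  n <- 2048
  fs <- 7
  spec <- rep(0, n)
  f <- (0:(n - 1)) * fs / n
  keep <- (f >= 0.11 & f <= 0.22) | (f >= fs - 0.22 & f <= fs - 0.11)
  phase <- runif(n, 0, 2 * pi)
  spec[keep] <- exp(1i * phase[keep])
  x <- Re(fft(spec, inverse = TRUE))
  d <- wavelet_decompose(x, level = 8, fs_hz = fs)
  vars <- vapply(d$details, var, 0)
  expect_equal(names(which.max(vars)), "D5")
  rng <- level_frequency_range(5, fs)
  expect_true(rng[1] <= 0.11 && rng[2] >= 0.21)
})

test_that("dyadic level frequency ranges match the printed table at 7 Hz", {
  expect_equal(level_frequency_range(1, 7), c(1.75, 3.5))
  expect_equal(level_frequency_range(5, 7), c(0.109375, 0.21875))
  expect_equal(level_frequency_range(8, 7), c(7 / 512, 7 / 256))
  printed <- list(c(1.75, 3.5), c(0.88, 1.75), c(0.44, 0.88), c(0.22, 0.44),
                  c(0.11, 0.22), c(0.05, 0.11), c(0.03, 0.05), c(0.01, 0.03))
  for (n in 1:8)
    expect_equal(round(level_frequency_range(n, 7), 2), printed[[n]])
  expect_error(level_frequency_range(0, 7), "1..8")
  expect_error(level_frequency_range(9, 7), "1..8")
})

test_that("wavelet Shannon entropy follows the unnormalized formula", {
  expect_equal(wavelet_entropy(numeric(0)), 0)
  expect_equal(wavelet_entropy(c(0, 0, 0)), 0)
  expect_equal(wavelet_entropy(c(1, 1)), 0)
  expect_equal(wavelet_entropy(c(2, 2)), -16)
  set.seed(1)
  cc <- rnorm(64)
  expect_equal(wavelet_entropy(cc), -sum(cc^2 * log2(cc^2)))
})

test_that("coefficient moments use unbiased variance and non-excess kurtosis", {
  m <- coef_moments(c(1, 1, 1, 1))
  expect_equal(m$mean, 1)
  expect_equal(m$variance, 0)
  expect_true(is.na(m$kurtosis))
  m2 <- coef_moments(c(0, 2, 0, 2))
  expect_equal(m2$mean, 1)
  expect_equal(m2$variance, 4 / 3)
  set.seed(8)
  m3 <- coef_moments(rnorm(1e5))
  expect_equal(m3$kurtosis, 3, tolerance = 0.1)
})

test_that("multiscale beta is the log2 variance slope of adjacent detail pairs", {
  fake <- structure(list(details = list(D1 = c(-1, 1, -1, 1),      # var 4/3
                                        D2 = 2 * c(-1, 1, -1, 1)), # var 16/3
                         level = 2),
                    class = "wavelet_decomposition")
  expect_equal(multiscale_beta(fake, c(2, 1)), 2)
  fake$details$D2 <- fake$details$D1
  expect_equal(multiscale_beta(fake, c(2, 1)), 0)
  fake$details$D2 <- rep(1, 4)
  expect_true(is.na(multiscale_beta(fake, c(2, 1))))
  expect_error(multiscale_beta(fake, c(3, 1)), "adjacent")
})

test_that("the feature vector has exactly 43 named finite entries", {
  w <- sim_hrv_window(60, noise_sd = 0.01, seed = 21)
  fv <- wavelet_features(w)
  expect_length(fv, 43)
  expect_true(all(is.finite(fv)))
  expect_true(all(c("entropy_A8", "kurtosis_D2", "beta_D8D7", "beta_D2D1",
                    "variance_D5", "mean_A8") %in% names(fv)))
  expect_equal(sum(startsWith(names(fv), "beta_")), 7)
  expect_identical(fv, wavelet_features(w))   # determinism
})

test_that("rescaling a window changes entropy and variance but not beta", {
  w <- sim_hrv_window(60, noise_sd = 0.01, seed = 22)
  fv1 <- wavelet_features(w)
  w2 <- hrv_series(2 * w$values, w$fs_hz, window_length_s = 60)
  fv2 <- wavelet_features(w2)
  betas <- startsWith(names(fv1), "beta_")
  expect_equal(fv2[betas], fv1[betas], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(fv2["entropy_A8"], fv1["entropy_A8"])))
  expect_equal(unname(fv2["variance_A8"]), unname(4 * fv1["variance_A8"]))
})

test_that("degenerate levels impute kurtosis 3 and beta 0 with a warning", {
  x <- rep(1, 420)   # constant window: every detail level is all-zero
  expect_warning(fv <- wavelet_features(x), "degenerate")
  expect_length(fv, 43)
  expect_true(all(is.finite(fv)))
  expect_equal(unname(fv["kurtosis_D3"]), 3)
  expect_equal(unname(fv["beta_D8D7"]), 0)
})
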