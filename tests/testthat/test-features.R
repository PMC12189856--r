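# Feature operators are verified against independent oracles: a direct
# rectangular periodogram (Parseval), an O(n^2) loop-based template counter
# for ApEn, frozen multi-level coefficients from an independent reference
# DWT implementation, and closed forms for the entropy/moment features.

test_that("Welch PSD: pure tone peaks at its bin, zero input is zero", {
  fs <- 128
  x <- sin(2 * pi * 10 * (0:255) / fs)
  est <- welch_psd(x, fs)
  expect_equal(est$frequencies[which.max(est$psd)], 10)
  expect_true(all(welch_psd(numeric(256), fs)$psd == 0))
  expect_error(welch_psd(rnorm(64), fs), "shorter",
               class = "ctesm_validation_error")
})

test_that("Welch PSD of white noise is flat and Parseval-consistent", {
  withr::with_seed(3, {
    fs <- 128
    x <- rnorm(fs * 8)
    est <- welch_psd(x, fs)
    df <- diff(est$frequencies[1:2])
    # total power matches the direct periodogram oracle's within 10%
    oracle <- periodogram_oracle(x, fs)
    df_o <- diff(oracle$frequencies[1:2])
    expect_lt(abs(sum(est$psd) * df / (sum(oracle$psd) * df_o) - 1), 0.1)
    expect_lt(abs(sum(est$psd) * df / stats::var(x) - 1), 0.1)
    # flatness: mean PSD in the lower and upper half-band agree within 25%
    lower <- est$psd[est$frequencies > 1 & est$frequencies <= 32]
    upper <- est$psd[est$frequencies > 32 & est$frequencies < 63]
    expect_lt(abs(mean(lower) / mean(upper) - 1), 0.25)
  })
})

test_that("band power is the mean PSD over band bins", {
  est <- structure(list(frequencies = 0:64, psd = rep(3, 65)),
                   class = "ctesm_psd")
  expect_equal(band_power(est, band_definition("x", 8, 13)), 3)
  # 10 Hz tone: alpha dominates every other band
  x <- sin(2 * pi * 10 * (0:511) / 128)
  estx <- welch_psd(x, 128)
  powers <- vapply(eeg_bands()$name, function(b) band_power(estx, b),
                   numeric(1))
  expect_identical(names(which.max(powers)), "alpha")
  expect_gt(powers["alpha"], 50 * max(powers[names(powers) != "alpha"]))
  # a band with no bins errors
  est_coarse <- welch_psd(x, 128, segment_s = 0.25)   # 4 Hz resolution
  expect_error(band_power(est_coarse, band_definition("narrow", 9, 11)),
               "no frequency bins", class = "ctesm_validation_error")
})

test_that("beta/alpha ratio handles the degenerate denominator", {
  expect_equal(band_ratio(2, 1), 2)
  expect_equal(band_ratio(0, 1), 0)
  expect_equal(band_ratio(5, 5), 1)
  r <- band_ratio(1, 0)
  expect_true(isTRUE(attr(r, "flagged")))
  expect_equal(as.numeric(r), 1e12)
})

test_that("median frequency: tone, symmetric spectrum, white noise", {
  x <- sin(2 * pi * 10 * (0:511) / 128)
  expect_equal(median_frequency(welch_psd(x, 128)), 10)
  # constructed PSD symmetric about 20 Hz
  freqs <- 0:40
  psd <- exp(-(freqs - 20)^2 / 8)
  est <- structure(list(frequencies = freqs, psd = psd), class = "ctesm_psd")
  expect_lt(abs(median_frequency(est) - 20), 1 + 1e-9)
  # flat spectrum: median at half of Nyquist
  withr::with_seed(8, {
    w <- rnorm(128 * 30)
    expect_lt(abs(median_frequency(welch_psd(w, 128)) - 32), 3)
  })
  est0 <- structure(list(frequencies = 0:4, psd = numeric(5)),
                    class = "ctesm_psd")
  expect_error(median_frequency(est0), "zero total power",
               class = "ctesm_validation_error")
})

test_that("spectral entropy matches its closed forms", {
  mk <- function(psd) structure(
    list(frequencies = seq_along(psd) - 1, psd = psd), class = "ctesm_psd")
  expect_equal(spectral_entropy(mk(c(0, 5, 0, 0))), 0)        # one bin
  expect_equal(spectral_entropy(mk(rep(2, 16))), 4)           # log2(16)
  expect_equal(spectral_entropy(mk(c(1, 1))), 1)              # two equal bins
  expect_error(spectral_entropy(mk(numeric(4))), "zero total power",
               class = "ctesm_validation_error")
})

test_that("wavelet level means match the reference DWT implementation", {
  # frozen from an independent periodized db4 wavedec on these vectors
  x <- round(sin((0:63) * 0.35) + 0.25 * cos((0:63) * 1.3), 6)
  wm <- wavelet_level_means(x, levels = 3)
  expect_equal(unname(wm), c(0.10268777042659835, 0.28169978362795467,
                             1.2889189228198281, 1.291018765763162),
               tolerance = 1e-12)
  # odd length at an interior level (100 -> 50 -> 25 -> pad)
  x2 <- round(cos((0:99) * 0.21) + 0.1 * sin((0:99) * 2.2), 6)
  wm2 <- wavelet_level_means(x2, levels = 3)
  expect_equal(unname(wm2), c(0.09459032677096964, 0.07921777235898357,
                              0.256368533980226, 1.7816686887329956),
               tolerance = 1e-12)
})

test_that("wavelet decomposition is orthonormal and homogeneous", {
  withr::with_seed(4, {
    x <- rnorm(256)
    dec <- dwt_decompose(x, 4)
    energy <- sum(unlist(dec$details)^2) + sum(dec$approx^2)
    expect_equal(energy, sum(x^2), tolerance = 1e-9)
    expect_equal(wavelet_level_means(3 * x, 4),
                 3 * wavelet_level_means(x, 4), tolerance = 1e-12)
    expect_true(all(wavelet_level_means(numeric(64), 3) == 0))
  })
  expect_error(dwt_decompose(rnorm(32), 6), "too large",
               class = "ctesm_validation_error")
})

test_that("approximate entropy equals the O(n^2) counting oracle", {
  withr::with_seed(6, {
    for (n in c(80, 150, 200)) {
      x <- rnorm(n)
      r <- 0.2 * sqrt(mean((x - mean(x))^2))
      expect_equal(approximate_entropy(x, m = 2, r_frac = 0.2),
                   apen_oracle(x, 2, r), tolerance = 1e-10)
    }
    x <- runif(120)
    r1 <- 0.3 * sqrt(mean((x - mean(x))^2))
    expect_equal(approximate_entropy(x, m = 1, r_frac = 0.3),
                 apen_oracle(x, 1, r1), tolerance = 1e-10)
  })
})

test_that("ApEn ranks periodic below noise and flags constant input", {
  withr::with_seed(12, {
    periodic <- rep(c(0, 1, 0, -1), length.out = 100)
    noise <- rnorm(100)
    expect_lt(approximate_entropy(periodic), approximate_entropy(noise))
  })
  const <- approximate_entropy(rep(2, 50))
  expect_equal(as.numeric(const), 0)
  expect_true(isTRUE(attr(const, "flagged")))
})

test_that("amplitude-histogram entropy mode behaves as a Shannon entropy", {
  withr::with_seed(13, {
    x <- rnorm(500)
    h <- approximate_entropy(x, mode = "amplitude", n_bins = 10)
    expect_gte(h, 0)
    expect_lte(h, log(10) + 1e-12)
  })
})

test_that("moment and sign-change features match their definitions", {
  expect_equal(skewness(c(-1, 0, 1)), 0)
  expect_equal(zero_crossing_rate(c(1, -1, 1, -1)), 1)
  expect_equal(zero_crossing_rate(c(1, 2, 3)), 0)
  withr::with_seed(14, {
    z <- rnorm(2e5)
    expect_lt(abs(kurtosis(z) - 3), 0.1)   # population convention, no -3
    expect_lt(abs(skewness(z)), 0.05)
  })
  # oracle: direct population moments on a fixed asymmetric vector
  v <- c(0, 0, 0, 1, 5)
  mu <- mean(v); s <- sqrt(mean((v - mu)^2))
  expect_equal(skewness(v), mean(((v - mu) / s)^3))
  expect_equal(kurtosis(v), mean(((v - mu) / s)^4))
  expect_error(skewness(rep(1, 10)), "zero variance",
               class = "ctesm_validation_error")
})

test_that("extraction yields one instance per frame with stable naming", {
  co <- beta_cohort()
  fs <- window_frames(co[[1]])
  inst <- extract_features(fs)
  expect_length(inst, length(fs$frames))
  expect_identical(dim(inst[[1]]$matrix), c(8L, 18L))
  expect_identical(inst[[1]]$feature_names,
                   colnames(inst[[1]]$matrix))
  expect_identical(inst[[1]]$feature_names[1:6],
                   c("power_delta", "power_theta", "power_alpha",
                     "power_beta", "power_gamma", "beta_alpha_ratio"))
  # determinism
  inst2 <- extract_features(fs)
  expect_identical(inst[[3]]$matrix, inst2[[3]]$matrix)
  # channel permutation permutes rows identically
  rec <- co[[1]]
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  rec_p <- rec
  rec_p$signal <- rec$signal[, perm]
  inst_p <- extract_features(window_frames(rec_p))
  expect_equal(unname(inst_p[[1]]$matrix), unname(inst[[1]]$matrix[perm, ]))
})

test_that("undefined features become flagged sentinels, channels kept", {
  rec <- generate_cohort(tiny_cohort_spec(n = 1, channels = 2,
                                          duration = 2))[[1]]
  rec$signal[, 2] <- 0                    # flat channel
  inst <- extract_features(window_frames(rec))
  m <- inst[[1]]$matrix
  expect_identical(nrow(m), 2L)
  expect_true(all(is.finite(m)))
  expect_equal(unname(m[2, c("skewness", "kurtosis", "apen")]), c(0, 0, 0))
  expect_true("2" %in% names(inst[[1]]$flags))
})

test_that("amplitude scaling transforms each feature as specified", {
  rec <- generate_cohort(tiny_cohort_spec(n = 1, channels = 3,
                                          duration = 4, seed = 31))[[1]]
  c_scale <- 2.5
  rec_s <- rec
  rec_s$signal <- rec$signal * c_scale
  a <- extract_features(window_frames(rec))[[1]]$matrix
  b <- extract_features(window_frames(rec_s))[[1]]$matrix
  pow_cols <- paste0("power_", eeg_bands()$name)
  wav_cols <- grep("^wavelet_", colnames(a), value = TRUE)
  inv_cols <- c("beta_alpha_ratio", "median_frequency", "spectral_entropy",
                "apen", "skewness", "kurtosis", "zcr")
  expect_equal(b[, pow_cols], c_scale^2 * a[, pow_cols], tolerance = 1e-9)
  expect_equal(b[, wav_cols], c_scale * a[, wav_cols], tolerance = 1e-9)
  expect_equal(b[, inv_cols], a[, inv_cols], tolerance = 1e-9)
})

test_that("feature ranges respect their mathematical bounds", {
  co <- beta_cohort()
  inst <- extract_features(window_frames(co[[2]]))
  for (i in seq_along(inst)) {
    m <- inst[[i]]$matrix
    expect_true(all(m[, paste0("power_", eeg_bands()$name)] >= 0))
    expect_true(all(m[, "zcr"] >= 0 & m[, "zcr"] <= 1))
    n_bins <- 128 %/% 2 + 1
    expect_true(all(m[, "spectral_entropy"] >= 0 &
                    m[, "spectral_entropy"] <= log2(n_bins)))
  }
})

test_that("beta features separate the classes on a beta-effect cohort", {
  co <- beta_cohort()
  labs <- cohort_labels(co)
  # per-subject mean over frames and channels of the two beta features
  subj_means <- t(vapply(co, function(r) {
    inst <- extract_features(window_frames(r))
    m <- vapply(inst, function(ii) {
      colMeans(ii$matrix[, c("power_beta", "beta_alpha_ratio")])
    }, numeric(2))
    rowMeans(m)
  }, numeric(2)))
  for (j in 1:2) {
    tt <- stats::t.test(subj_means[labs == "PD", j],
                        subj_means[labs == "HC", j],
                        alternative = "greater")
    expect_lt(tt$p.value, 0.01)
  }
})
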