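test_that("cohort generation is reproducible and label-balanced", {
  spec <- tiny_cohort_spec(n = 3, seed = 5)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_length(c1, 6)
  expect_identical(cohort_labels(c1), c(rep("PD", 3), rep("HC", 3)))
  for (i in seq_along(c1)) {
    expect_identical(c1[[i]]$signal, c2[[i]]$signal)
  }
  n <- round(spec$duration_s * spec$sampling_rate_hz)
  expect_true(all(vapply(c1, function(r) nrow(r$signal) == n, logical(1))))
  expect_true(all(vapply(c1, function(r) all(is.finite(r$signal)), logical(1))))
})

test_that("unbalanced class sizes are honoured", {
  co <- generate_cohort(cohort_spec(
    n_subjects_per_class = c(PD = 15, HC = 16), n_channels = 2,
    sampling_rate_hz = 128, duration_s = 2, noise_sd = 0,
    background_rms = 0, seed = 1))
  expect_length(co, 31)
  expect_identical(unname(table(cohort_labels(co))["PD"]), 15L)
  expect_identical(unname(table(cohort_labels(co))["HC"]), 16L)
})

test_that("invalid spec fields raise validation errors naming the field", {
  expect_error(cohort_spec(n_subjects_per_class = 0), "n_subjects_per_class",
               class = "ctesm_validation_error")
  expect_error(cohort_spec(sampling_rate_hz = 60), "sampling_rate_hz",
               class = "ctesm_validation_error")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd",
               class = "ctesm_validation_error")
  expect_error(cohort_spec(class_effect = list(PD = c(beta = -2),
                                               HC = c())),
               "class_effect", class = "ctesm_validation_error")
  expect_error(tiny_cohort_spec(effect_channels = c(1, 99)),
               "effect_channels", class = "ctesm_validation_error")
})

test_that("a pure single-band component dominates at its pinned frequency", {
  co <- generate_cohort(cohort_spec(
    n_subjects_per_class = 1, n_channels = 1, sampling_rate_hz = 128,
    duration_s = 4, band_amplitudes = c(alpha = 1),
    fixed_frequencies = c(alpha = 10), background_rms = 0, noise_sd = 0,
    seed = 2))
  x <- co[[1]]$signal[, 1]
  est <- periodogram_oracle(x, 128)
  expect_equal(est$frequencies[which.max(est$psd)], 10)
})

test_that("spectral fidelity: >=95% of Welch power falls in the component band", {
  co <- generate_cohort(cohort_spec(
    n_subjects_per_class = 1, n_channels = 1, sampling_rate_hz = 128,
    duration_s = 8, band_amplitudes = c(beta = 1), background_rms = 0,
    noise_sd = 0, seed = 9))
  est <- welch_psd(co[[1]]$signal[, 1], 128)
  in_beta <- est$frequencies >= 13 & est$frequencies < 30
  expect_gt(sum(est$psd[in_beta]) / sum(est$psd), 0.95)
})

test_that("a beta class effect raises PD beta power (periodogram oracle)", {
  co <- beta_cohort()
  labs <- cohort_labels(co)
  beta_pow <- vapply(co, function(r) {
    est <- periodogram_oracle(r$signal[, 1], r$sampling_rate_hz)
    sel <- est$frequencies >= 13 & est$frequencies < 30
    mean(est$psd[sel])
  }, numeric(1))
  expect_gt(mean(beta_pow[labs == "PD"]), mean(beta_pow[labs == "HC"]))
})

test_that("the 1/f background has roughly the requested spectral slope", {
  co <- generate_cohort(cohort_spec(
    n_subjects_per_class = 1, n_channels = 1, sampling_rate_hz = 128,
    duration_s = 60, band_amplitudes = c(alpha = 0), background_rms = 5,
    noise_sd = 0, background_exponent = 1, seed = 3))
  est <- welch_psd(co[[1]]$signal[, 1], 128, segment_s = 4)
  sel <- est$frequencies >= 1 & est$frequencies <= 40
  fit <- stats::lm(log(est$psd[sel]) ~ log(est$frequencies[sel]))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1), 0.35)
})

test_that("the class effect can be restricted to a channel subset", {
  co <- generate_cohort(cohort_spec(
    n_subjects_per_class = 4, n_channels = 6, sampling_rate_hz = 128,
    duration_s = 8, class_effect = list(PD = c(beta = 3), HC = c(beta = 1)),
    effect_channels = 1:3, background_rms = 0, noise_sd = 0.5, seed = 21))
  labs <- cohort_labels(co)
  beta_by_channel <- function(ch) {
    vapply(co, function(r) {
      est <- periodogram_oracle(r$signal[, ch], 128)
      mean(est$psd[est$frequencies >= 13 & est$frequencies < 30])
    }, numeric(1))
  }
  on_effect <- beta_by_channel(2)
  off_effect <- beta_by_channel(5)
  ratio_on <- mean(on_effect[labs == "PD"]) / mean(on_effect[labs == "HC"])
  ratio_off <- mean(off_effect[labs == "PD"]) / mean(off_effect[labs == "HC"])
  expect_gt(ratio_on, 4)       # amplitude x3 => power x9, modulo jitter
  expect_lt(abs(ratio_off - 1), 0.5)
})
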