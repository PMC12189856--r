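# Shared fixtures. Cohorts are small (8 channels, 128 Hz) so the whole
# suite stays fast; the feature mathematics is identical at any scale.

tiny_cohort_spec <- function(n = 2, channels = 4, seed = 7, duration = 10,
                             ...) {
  cohort_spec(n_subjects_per_class = n, n_channels = channels,
              sampling_rate_hz = 128, duration_s = duration, seed = seed, ...)
}

# One cached mid-size cohort with a beta-band class effect, reused by the
# feature-separation and model tests.
beta_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_spec(
        n_subjects_per_class = 10, n_channels = 8, sampling_rate_hz = 128,
        duration_s = 10, class_effect = list(PD = c(beta = 3), HC = c(beta = 1)),
        seed = 42))
    }
    cache
  }
})

# A tiny classifier configuration that trains in seconds.
tiny_model_config <- function(...) {
  ctesm_config(conv_filters = c(8L, 16L), kernel_size = 3L, pool_size = 2L,
               n_heads = 2L, d_k = 8L, ff_dim = 16L, lstm_units = 16L, ...)
}

# Hand-built feature instances: two linearly separable classes.
separable_instances <- function(n_per_class = 30, channels = 8, features = 6,
                                shift = 3, seed = 1) {
  withr::with_seed(seed, {
    out <- vector("list", 2 * n_per_class)
    for (i in seq_len(2 * n_per_class)) {
      lab <- if (i <= n_per_class) "A" else "B"
      m <- matrix(rnorm(channels * features), channels, features)
      if (lab == "B") m <- m + shift
      out[[i]] <- ctesm:::new_feature_instance(
        m, sprintf("f%d", seq_len(features)), lab,
        sprintf("S%02d", i), 1L)
    }
    out
  })
}

# Direct rectangular-window periodogram: the independent spectral oracle.
periodogram_oracle <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2 / (fs * n)
  nf <- n %/% 2 + 1
  p1 <- P[seq_len(nf)]
  dbl <- rep(2, nf); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  list(frequencies = (0:(nf - 1)) * fs / n, psd = p1 * dbl)
}

# O(n^2) loop-based template-matching entropy: the independent ApEn oracle.
apen_oracle <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nm <- n - mm + 1
    cnt <- numeric(nm)
    for (i in seq_len(nm)) {
      for (j in seq_len(nm)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) {
          cnt[i] <- cnt[i] + 1
        }
      }
    }
    mean(log(cnt / nm))
  }
  phi(m) - phi(m + 1)
}
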