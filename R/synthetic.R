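#' Specify a synthetic two-class EEG cohort
#'
#' Describes a resting-state cohort of Parkinson's disease (PD) and healthy
#' control (HC) subjects whose multichannel EEG is simulated as a sum of
#' band-limited oscillations, a 1/f-shaped background, and white Gaussian
#' sensor noise. Class structure enters through per-band amplitude
#' multipliers (`class_effect`), by default an elevated beta-band amplitude
#' in the PD class, emulating the beta-band disruption characteristic of
#' Parkinsonian cortical circuits.
#'
#' @param n_subjects_per_class Number of subjects in each class. Either a
#'   single positive integer or a named integer vector such as
#'   `c(PD = 15, HC = 16)` for unbalanced cohorts.
#' @param n_channels Number of EEG channels (default 40, a standard 10-20
#'   high-density montage).
#' @param sampling_rate_hz Sampling rate in Hz (default 500). Must exceed
#'   twice the highest band edge.
#' @param duration_s Recording duration in seconds.
#' @param class_effect Named list mapping class label to a named vector of
#'   per-band amplitude multipliers, e.g.
#'   `list(PD = c(beta = 2.5), HC = c())`. Unstated bands default to 1.
#' @param effect_channels Channel indices expressing the class effect
#'   (default `NULL`: all channels). Parkinsonian beta disruption is
#'   topographically localized over sensorimotor cortex, so restricting the
#'   effect to a contiguous electrode subset emulates the spatial structure
#'   real cohorts show; channels outside the subset use multiplier 1.
#' @param band_amplitudes Named vector of baseline per-band component
#'   amplitudes (arbitrary microvolt-scale units). Only the named bands are
#'   synthesized, so a single-component signal is obtained by naming one band.
#' @param fixed_frequencies Optional named vector pinning the component
#'   frequency of a band (Hz); unpinned bands draw their frequency uniformly
#'   within the band per subject.
#' @param background_rms Root-mean-square amplitude of the 1/f background
#'   (0 disables it).
#' @param noise_sd Standard deviation of additive white Gaussian noise.
#' @param background_exponent Spectral slope of the background: power falls
#'   off as `1/f^exponent` (default 1).
#' @param seed Integer seed; the full cohort is a deterministic function of
#'   the spec.
#' @return An object of class `ctesm_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_per_class = 15,
                        n_channels = 40,
                        sampling_rate_hz = 500,
                        duration_s = 30,
                        class_effect = list(PD = c(beta = 2.5),
                                            HC = c(beta = 1)),
                        effect_channels = NULL,
                        band_amplitudes = c(delta = 20, theta = 10,
                                            alpha = 15, beta = 6, gamma = 3),
                        fixed_frequencies = NULL,
                        background_rms = 5,
                        noise_sd = 1,
                        background_exponent = 1,
                        seed = 1L) {
  bands <- eeg_bands()
  if (is.null(names(n_subjects_per_class))) {
    check_positive_scalar(n_subjects_per_class, "n_subjects_per_class",
                          integer = TRUE)
    n_per_class <- c(PD = n_subjects_per_class, HC = n_subjects_per_class)
  } else {
    if (!all(sort(names(n_subjects_per_class)) == c("HC", "PD"))) {
      stop_validation("field 'n_subjects_per_class' must be named PD and HC")
    }
    for (cl in names(n_subjects_per_class)) {
      check_positive_scalar(n_subjects_per_class[[cl]],
                            paste0("n_subjects_per_class[", cl, "]"),
                            integer = TRUE)
    }
    n_per_class <- n_subjects_per_class[c("PD", "HC")]
  }
  check_positive_scalar(n_channels, "n_channels", integer = TRUE)
  check_positive_scalar(sampling_rate_hz, "sampling_rate_hz")
  check_positive_scalar(duration_s, "duration_s")
  check_positive_scalar(background_rms, "background_rms", allow_zero = TRUE)
  check_positive_scalar(noise_sd, "noise_sd", allow_zero = TRUE)
  if (!is.numeric(background_exponent) || length(background_exponent) != 1L) {
    stop_validation("field 'background_exponent' must be a numeric scalar")
  }
  check_positive_scalar(seed, "seed", integer = TRUE, allow_zero = TRUE)

  if (is.null(names(band_amplitudes)) ||
      !all(names(band_amplitudes) %in% bands$name)) {
    stop_validation(
      "field 'band_amplitudes' must be named with canonical band names")
  }
  if (any(band_amplitudes < 0)) {
    stop_validation("field 'band_amplitudes' must be non-negative")
  }
  used <- bands[bands$name %in% names(band_amplitudes), ]
  if (sampling_rate_hz <= 2 * max(used$high_hz)) {
    stop_validation(sprintf(
      "field 'sampling_rate_hz' (%g) must exceed twice the highest band edge (%g)",
      sampling_rate_hz, max(used$high_hz)))
  }
  if (!is.list(class_effect) ||
      !all(sort(names(class_effect)) == c("HC", "PD"))) {
    stop_validation("field 'class_effect' must be a list with elements PD and HC")
  }
  for (cl in names(class_effect)) {
    ce <- class_effect[[cl]]
    if (length(ce)) {
      if (is.null(names(ce)) || !all(names(ce) %in% bands$name)) {
        stop_validation(sprintf(
          "field 'class_effect[[%s]]' must be named with canonical band names", cl))
      }
      if (any(ce <= 0)) {
        stop_validation(sprintf(
          "field 'class_effect[[%s]]' multipliers must be > 0", cl))
      }
    }
  }
  if (!is.null(effect_channels)) {
    if (!is.numeric(effect_channels) ||
        any(effect_channels < 1 | effect_channels > n_channels) ||
        anyDuplicated(effect_channels)) {
      stop_validation(
        "field 'effect_channels' must be distinct channel indices in range")
    }
    effect_channels <- as.integer(effect_channels)
  }
  if (!is.null(fixed_frequencies)) {
    if (is.null(names(fixed_frequencies)) ||
        !all(names(fixed_frequencies) %in% names(band_amplitudes))) {
      stop_validation(
        "field 'fixed_frequencies' must be named with synthesized band names")
    }
  }

  structure(
    list(
      n_per_class = n_per_class,
      n_channels = as.integer(n_channels),
      sampling_rate_hz = sampling_rate_hz,
      duration_s = duration_s,
      class_effect = class_effect,
      effect_channels = effect_channels,
      band_amplitudes = band_amplitudes,
      fixed_frequencies = fixed_frequencies,
      background_rms = background_rms,
      noise_sd = noise_sd,
      background_exponent = background_exponent,
      seed = as.integer(seed),
      bands = bands
    ),
    class = "ctesm_cohort_spec"
  )
}

new_recording <- function(signal, sampling_rate_hz, label, subject_id) {
  structure(
    list(signal = signal, sampling_rate_hz = sampling_rate_hz,
         label = label, subject_id = subject_id),
    class = "ctesm_recording"
  )
}

#' @export
print.ctesm_recording <- function(x, ...) {
  cat(sprintf("<ctesm_recording> %s [%s]: %d samples x %d channels @ %g Hz\n",
              x$subject_id, x$label, nrow(x$signal), ncol(x$signal),
              x$sampling_rate_hz))
  invisible(x)
}

# 1/f-shaped background: white noise whose FFT amplitudes are shaped by
# f^(-exponent/2), rescaled to a target RMS.
one_over_f_background <- function(n, fs, exponent, rms) {
  if (rms == 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f[f > fs / 2] <- fs - f[f > fs / 2]   # mirror to |f|
  shape <- c(0, f[-1]^(-exponent / 2))  # kill DC
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x * rms / sqrt(mean(x^2))
}

#' Generate a synthetic EEG cohort
#'
#' Each subject's recording is the sum of one sinusoidal component per
#' synthesized band (frequency drawn uniformly within the band per subject,
#' unless pinned; independent random phase per channel; amplitude = baseline
#' band amplitude x class multiplier x mild per-channel jitter), a 1/f-shaped
#' stochastic background, and white Gaussian noise. Subjects use independent
#' RNG streams derived from the spec seed by counter, so the cohort is
#' reproducible and subjects are mutually independent.
#'
#' @param spec A [cohort_spec()].
#' @return A list of [ctesm_recording][cohort_spec] objects (class
#'   `ctesm_cohort`), labels `PD`/`HC`, with the spec attached as an
#'   attribute.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(
#'   n_subjects_per_class = 2, n_channels = 4, sampling_rate_hz = 128,
#'   duration_s = 5, seed = 7))
#' length(cohort)
generate_cohort <- function(spec) {
  if (!inherits(spec, "ctesm_cohort_spec")) {
    stop_validation("'spec' must be created by cohort_spec()")
  }
  n_samples <- round(spec$duration_s * spec$sampling_rate_hz)
  tt <- (0:(n_samples - 1)) / spec$sampling_rate_hz
  band_names <- names(spec$band_amplitudes)
  bands <- spec$bands[match(band_names, spec$bands$name), ]

  recs <- list()
  counter <- 0L
  for (cl in c("PD", "HC")) {
    mult <- spec$class_effect[[cl]]
    for (s in seq_len(spec$n_per_class[[cl]])) {
      counter <- counter + 1L
      sid <- sprintf("%s%02d", cl, s)
      sig <- with_seed(derive_seed(spec$seed, counter), {
        m <- matrix(0, n_samples, spec$n_channels)
        for (b in seq_along(band_names)) {
          bn <- band_names[b]
          f0 <- if (!is.null(spec$fixed_frequencies) &&
                    bn %in% names(spec$fixed_frequencies)) {
            spec$fixed_frequencies[[bn]]
          } else {
            # draw from the band interior (10% edge margin): physiological
            # rhythms peak inside their band, and an edge component would be
            # attributed to the neighbouring band at typical analysis
            # resolution, making the construct ambiguous
            margin <- 0.1 * (bands$high_hz[b] - bands$low_hz[b])
            stats::runif(1, bands$low_hz[b] + margin, bands$high_hz[b] - margin)
          }
          base_amp <- spec$band_amplitudes[[bn]]
          band_mult <- if (bn %in% names(mult)) mult[[bn]] else 1
          for (ch in seq_len(spec$n_channels)) {
            expressed <- is.null(spec$effect_channels) ||
              ch %in% spec$effect_channels
            amp0 <- base_amp * (if (expressed) band_mult else 1)
            phase <- stats::runif(1, 0, 2 * pi)
            amp <- amp0 * stats::runif(1, 0.8, 1.2)
            m[, ch] <- m[, ch] + amp * sin(2 * pi * f0 * tt + phase)
          }
        }
        for (ch in seq_len(spec$n_channels)) {
          m[, ch] <- m[, ch] + one_over_f_background(
            n_samples, spec$sampling_rate_hz,
            spec$background_exponent, spec$background_rms)
        }
        if (spec$noise_sd > 0) {
          m <- m + matrix(stats::rnorm(n_samples * spec$n_channels,
                                       sd = spec$noise_sd),
                          n_samples, spec$n_channels)
        }
        colnames(m) <- sprintf("Ch%02d", seq_len(spec$n_channels))
        m
      })
      stopifnot(all(is.finite(sig)))
      recs[[counter]] <- new_recording(sig, spec$sampling_rate_hz, cl, sid)
    }
  }
  structure(recs, class = "ctesm_cohort", spec = spec)
}

#' @export
print.ctesm_cohort <- function(x, ...) {
  labs <- vapply(x, function(r) r$label, character(1))
  cat(sprintf("<ctesm_cohort> %d recordings (%s)\n", length(x),
              paste(sprintf("%s=%d", names(table(labs)), table(labs)),
                    collapse = ", ")))
  invisible(x)
}

#' Cohort labels
#' @param cohort A `ctesm_cohort` or list of recordings.
#' @return Character vector of per-recording class labels.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort, function(r) r$label, character(1))
}
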