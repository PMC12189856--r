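# Frame-wise biologically informed EEG features. Per frame-channel pair the
# extractor computes, in fixed order: mean PSD in the five canonical bands
# (Welch), beta/alpha power ratio, median frequency, spectral entropy,
# wavelet level means, approximate entropy, skewness, kurtosis and
# zero-crossing rate.

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram over Hann-tapered 50%-overlapping segments.
#' Each segment is mean-detrended, so the one-sided density integrates to
#' approximately the signal variance (Parseval, within taper bias).
#'
#' @param x Numeric vector (one frame of one channel).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param segment_s Segment length in seconds (default 1, giving >= 3
#'   averages within a 2 s frame at 50% overlap).
#' @param overlap Fractional segment overlap in `[0, 1)` (default 0.5).
#' @param detrend Subtract each segment's mean before tapering (default TRUE).
#' @return A `ctesm_psd`: list with `frequencies` (Hz, from 0 to Nyquist)
#'   and `psd` (power per Hz), plus the estimation parameters.
#' @export
welch_psd <- function(x, sampling_rate_hz, segment_s = 1, overlap = 0.5,
                      detrend = TRUE) {
  check_positive_scalar(sampling_rate_hz, "sampling_rate_hz")
  nper <- round(segment_s * sampling_rate_hz)
  if (length(x) < nper) {
    stop_validation(sprintf(
      "input length %d shorter than Welch segment (%d samples)",
      length(x), nper))
  }
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- hann_window(nper)
  scale_ <- 1 / (sampling_rate_hz * sum(w^2))
  n_freq <- nper %/% 2L + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    if (detrend) seg <- seg - mean(seg)
    P <- Mod(stats::fft(seg * w))^2 * scale_
    p1 <- P[seq_len(n_freq)]
    # one-sided: double everything except DC (and Nyquist when nper even)
    dbl <- rep(2, n_freq)
    dbl[1] <- 1
    if (nper %% 2L == 0L) dbl[n_freq] <- 1
    acc <- acc + p1 * dbl
  }
  structure(
    list(frequencies = (0:(n_freq - 1L)) * sampling_rate_hz / nper,
         psd = acc / length(starts),
         segment_s = segment_s, overlap = overlap, taper = "hann"),
    class = "ctesm_psd"
  )
}

#' Mean band power
#'
#' Mean of the PSD over the frequency bins falling in `[low_hz, high_hz)`
#' (the per-bin average over the band, not the integrated power).
#'
#' @param est A `ctesm_psd` from [welch_psd()].
#' @param band One-row band definition (see [band_definition()]), or a band
#'   name from [eeg_bands()].
#' @return Non-negative scalar.
#' @export
band_power <- function(est, band) {
  if (is.character(band)) {
    b <- eeg_bands()
    band <- b[b$name == band, ]
    if (!nrow(band)) stop_validation(sprintf("unknown band '%s'", band))
  }
  sel <- est$frequencies >= band$low_hz & est$frequencies < band$high_hz
  if (!any(sel)) {
    stop_validation(sprintf(
      "band %s [%g, %g) contains no frequency bins (resolution %g Hz)",
      band$name, band$low_hz, band$high_hz, diff(est$frequencies[1:2])))
  }
  mean(est$psd[sel])
}

#' Beta-to-alpha power ratio
#'
#' @param p_beta,p_alpha Non-negative band powers.
#' @param epsilon Floor applied to the denominator; when the alpha power
#'   falls at or below it the ratio is computed against `epsilon` and the
#'   result carries attribute `flagged = TRUE`.
#' @return Positive scalar (possibly flagged).
#' @export
band_ratio <- function(p_beta, p_alpha, epsilon = 1e-12) {
  if (p_alpha <= epsilon) {
    return(structure(p_beta / epsilon, flagged = TRUE))
  }
  p_beta / p_alpha
}

#' Median frequency
#'
#' Smallest frequency at which the cumulative PSD reaches half the total
#' power.
#'
#' @inheritParams band_power
#' @return Frequency in Hz.
#' @export
median_frequency <- function(est) {
  total <- sum(est$psd)
  if (total <= 0) {
    stop_validation("median frequency undefined: zero total power")
  }
  est$frequencies[which(cumsum(est$psd) >= 0.5 * total)[1]]
}

#' Spectral entropy
#'
#' Shannon entropy (bits) of the PSD normalized to a probability
#' distribution over frequency bins; zero-power bins contribute 0.
#'
#' @inheritParams band_power
#' @return Entropy in bits, in `[0, log2(n_bins)]`.
#' @export
spectral_entropy <- function(est) {
  total <- sum(est$psd)
  if (total <= 0) {
    stop_validation("spectral entropy undefined: zero total power")
  }
  p <- est$psd / total
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Approximate entropy
#'
#' Standard template-matching ApEn(m, r x SD): the difference
#' `Phi_m - Phi_(m+1)` of log mean self-match counts of length-m and
#' length-(m+1) templates within Chebyshev tolerance `r = r_frac * SD(x)`
#' (population SD). Lower values indicate a more regular, predictable
#' signal. A zero-variance input returns 0 (perfectly regular) with
#' attribute `flagged = TRUE`.
#'
#' An alternative reading of the amplitude-distribution entropy sometimes
#' labelled "ApEn" in the applied literature is available via
#' `mode = "amplitude"`: the Shannon entropy (nats) of a fixed-bin
#' amplitude histogram.
#'
#' @param x Numeric vector, length > m + 1.
#' @param m Embedding (template) length, default 2.
#' @param r_frac Tolerance as a fraction of the signal SD, default 0.2.
#' @param mode `"template"` (standard ApEn, default) or `"amplitude"`.
#' @param n_bins Histogram bins for `mode = "amplitude"` (default 10).
#' @return Non-negative scalar.
#' @export
approximate_entropy <- function(x, m = 2, r_frac = 0.2,
                                mode = c("template", "amplitude"),
                                n_bins = 10) {
  mode <- match.arg(mode)
  n <- length(x)
  if (n <= m + 1) {
    stop_validation(sprintf("input length %d too short for ApEn with m=%d", n, m))
  }
  if (r_frac <= 0) stop_validation("field 'r_frac' must be > 0")
  sdx <- sqrt(mean((x - mean(x))^2))
  if (sdx == 0) return(structure(0, flagged = TRUE))
  if (mode == "amplitude") {
    h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = n_bins + 1),
                        plot = FALSE)
    p <- h$counts / n
    p <- p[p > 0]
    return(-sum(p * log(p)))
  }
  r <- r_frac * sdx
  D <- abs(outer(x, x, "-")) <= r
  phi <- function(mm) {
    nm <- n - mm + 1L
    M <- D[seq_len(nm), seq_len(nm), drop = FALSE]
    if (mm > 1L) {
      for (k in seq_len(mm - 1L)) {
        M <- M & D[(1L + k):(nm + k), (1L + k):(nm + k), drop = FALSE]
      }
    }
    mean(log(rowSums(M) / nm))
  }
  phi(m) - phi(m + 1L)
}

#' Distribution-shape and sign-change features
#'
#' Population moments (denominator N, no excess adjustment for kurtosis —
#' a normal sample has kurtosis near 3) and the zero-crossing rate, the
#' fraction of adjacent sample pairs whose product is negative.
#'
#' @param x Numeric vector (length >= 2; skewness/kurtosis need SD > 0).
#' @return Scalar feature value.
#' @name shape_features
NULL

#' @rdname shape_features
#' @export
skewness <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) stop_validation("skewness undefined: zero variance")
  mean(((x - mu) / s)^3)
}

#' @rdname shape_features
#' @export
kurtosis <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) stop_validation("kurtosis undefined: zero variance")
  mean(((x - mu) / s)^4)
}

#' @rdname shape_features
#' @export
zero_crossing_rate <- function(x) {
  n <- length(x)
  if (n < 2L) stop_validation("zero-crossing rate needs length >= 2")
  sum(x[-1] * x[-n] < 0) / (n - 1)
}

#' Feature-extraction configuration
#'
#' @param bands Band definition table (default [eeg_bands()]).
#' @param welch_segment_s,welch_overlap Welch parameters (default 1 s, 50%).
#' @param wavelet_family,wavelet_levels DWT family and depth (default db4,
#'   5 detail levels).
#' @param apen_m,apen_r ApEn embedding length and tolerance fraction
#'   (default 2 and 0.2).
#' @param apen_mode `"template"` or `"amplitude"` (see
#'   [approximate_entropy()]).
#' @param sentinel Value recorded when a feature is undefined for a
#'   frame-channel pair (zero-variance input, zero total power); such
#'   entries are flagged in the instance's `flags` attribute. Default 0.
#' @param ratio_epsilon Denominator floor for the beta/alpha ratio.
#' @return A `ctesm_feature_config` list.
#' @export
feature_config <- function(bands = eeg_bands(),
                           welch_segment_s = 1, welch_overlap = 0.5,
                           wavelet_family = "db4", wavelet_levels = 5,
                           apen_m = 2, apen_r = 0.2,
                           apen_mode = c("template", "amplitude"),
                           sentinel = 0, ratio_epsilon = 1e-12) {
  bands <- validate_bands(bands)
  apen_mode <- match.arg(apen_mode)
  structure(
    list(bands = bands, welch_segment_s = welch_segment_s,
         welch_overlap = welch_overlap, wavelet_family = wavelet_family,
         wavelet_levels = as.integer(wavelet_levels),
         apen_m = as.integer(apen_m), apen_r = apen_r,
         apen_mode = apen_mode, sentinel = sentinel,
         ratio_epsilon = ratio_epsilon),
    class = "ctesm_feature_config"
  )
}

feature_names_for <- function(config) {
  c(paste0("power_", config$bands$name),
    "beta_alpha_ratio", "median_frequency", "spectral_entropy",
    paste0("wavelet_", c(sprintf("d%d", seq_len(config$wavelet_levels)),
                         sprintf("a%d", config$wavelet_levels))),
    "apen", "skewness", "kurtosis", "zcr")
}

new_feature_instance <- function(matrix_, feature_names, label, subject_id,
                                 frame_index, flags = NULL) {
  structure(
    list(matrix = matrix_, feature_names = feature_names, label = label,
         subject_id = subject_id, frame_index = frame_index,
         flags = flags),
    class = "ctesm_features"
  )
}

#' @export
print.ctesm_features <- function(x, ...) {
  cat(sprintf("<ctesm_features> %s frame %d [%s]: %d channels x %d features\n",
              x$subject_id, x$frame_index, x$label, nrow(x$matrix),
              ncol(x$matrix)))
  invisible(x)
}

extract_one_channel <- function(x, fs, config) {
  flags <- character(0)
  sdx <- sqrt(mean((x - mean(x))^2))
  est <- welch_psd(x, fs, config$welch_segment_s, config$welch_overlap)
  pb <- vapply(seq_len(nrow(config$bands)),
               function(i) band_power(est, config$bands[i, ]), numeric(1))
  names(pb) <- config$bands$name
  ratio <- band_ratio(pb[["beta"]], pb[["alpha"]], config$ratio_epsilon)
  if (isTRUE(attr(ratio, "flagged"))) flags <- c(flags, "beta_alpha_ratio")
  total <- sum(est$psd)
  if (total > 0) {
    mf <- median_frequency(est)
    se <- spectral_entropy(est)
  } else {
    mf <- config$sentinel
    se <- config$sentinel
    flags <- c(flags, "median_frequency", "spectral_entropy")
  }
  wl <- wavelet_level_means(x, config$wavelet_levels, config$wavelet_family)
  ae <- approximate_entropy(x, config$apen_m, config$apen_r,
                            mode = config$apen_mode)
  if (isTRUE(attr(ae, "flagged"))) flags <- c(flags, "apen")
  if (sdx > 0) {
    sk <- skewness(x)
    ku <- kurtosis(x)
  } else {
    sk <- config$sentinel
    ku <- config$sentinel
    flags <- c(flags, "skewness", "kurtosis")
  }
  list(values = c(pb, as.numeric(ratio), mf, se, wl, as.numeric(ae), sk, ku,
                  zero_crossing_rate(x)),
       flags = flags)
}

#' Extract feature instances from a frame set
#'
#' Computes the full feature vector for every frame-channel pair and
#' assembles one channels x features matrix per frame. Undefined features
#' (e.g. moments of a zero-variance channel) are recorded as the configured
#' sentinel and listed in the instance's `flags` element; channels are never
#' dropped.
#'
#' @param frameset A `ctesm_frameset` from [window_frames()].
#' @param config A [feature_config()].
#' @return List of `ctesm_features` instances, one per frame, each carrying
#'   the frame's label, subject and index.
#' @export
extract_features <- function(frameset, config = feature_config()) {
  if (!inherits(frameset, "ctesm_frameset")) {
    stop_validation("'frameset' must be a ctesm_frameset")
  }
  fn <- feature_names_for(config)
  fs <- frameset$sampling_rate_hz
  lapply(seq_along(frameset$frames), function(i) {
    fr <- frameset$frames[[i]]
    nc <- ncol(fr)
    m <- matrix(NA_real_, nc, length(fn),
                dimnames = list(colnames(fr), fn))
    flags <- list()
    for (ch in seq_len(nc)) {
      res <- extract_one_channel(fr[, ch], fs, config)
      m[ch, ] <- res$values
      if (length(res$flags)) flags[[as.character(ch)]] <- res$flags
    }
    stopifnot(all(is.finite(m)))
    new_feature_instance(m, fn, frameset$label, frameset$subject_id, i,
                         flags = if (length(flags)) flags else NULL)
  })
}

#' Extract features for a whole cohort
#'
#' Convenience wrapper: windows every recording and concatenates the
#' per-frame feature instances.
#'
#' @param cohort A `ctesm_cohort` or list of recordings.
#' @param frame_length_s,overlap_s Framing parameters (defaults 2 s / 1 s).
#' @param config A [feature_config()].
#' @return List of `ctesm_features` instances across all recordings.
#' @export
extract_cohort_features <- function(cohort, frame_length_s = 2, overlap_s = 1,
                                    config = feature_config()) {
  out <- lapply(cohort, function(rec) {
    extract_features(window_frames(rec, frame_length_s, overlap_s), config)
  })
  do.call(c, out)
}

#' Feature instances as a flat table
#'
#' @param instances List of `ctesm_features`.
#' @return Data frame with columns `subject_id`, `frame_index`, `label`,
#'   `channel`, then one column per feature.
#' @export
features_to_table <- function(instances) {
  do.call(rbind, lapply(instances, function(inst) {
    nc <- nrow(inst$matrix)
    cbind(
      data.frame(subject_id = rep(inst$subject_id, nc),
                 frame_index = rep(inst$frame_index, nc),
                 label = rep(inst$label, nc),
                 channel = rownames(inst$matrix) %||% as.character(seq_len(nc)),
                 stringsAsFactors = FALSE),
      as.data.frame(inst$matrix)
    )
  }))
}

#' Labels of a feature-instance collection
#' @param instances List of `ctesm_features`.
#' @return Character vector of labels, one per instance.
#' @export
instance_labels <- function(instances) {
  vapply(instances, function(i) i$label, character(1))
}
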