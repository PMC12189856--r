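#' Canonical EEG frequency bands
#'
#' Returns the conventional resting-state EEG band edges used throughout the
#' package: delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-45 Hz.
#' Beta (13-30 Hz) is the band with the best-established link to Parkinsonian
#' cortico-basal-ganglia disruption, which is why the synthetic cohort
#' generator expresses its class effect there by default.
#'
#' @return A data frame with columns `name`, `low_hz`, `high_hz`, one row per
#'   band, ordered by frequency.
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz = c(0.5, 4, 8, 13, 30),
    high_hz = c(4, 8, 13, 30, 45),
    stringsAsFactors = FALSE
  )
}

#' Define a frequency band
#'
#' @param name Band name (any label; the canonical five are in [eeg_bands()]).
#' @param low_hz,high_hz Band edges in Hz, `0 <= low_hz < high_hz`.
#' @return A one-row band definition data frame.
#' @export
band_definition <- function(name, low_hz, high_hz) {
  if (!is.character(name) || length(name) != 1L) {
    stop_validation("field 'name' must be a single string")
  }
  check_positive_scalar(low_hz, "low_hz", allow_zero = TRUE)
  check_positive_scalar(high_hz, "high_hz")
  if (low_hz >= high_hz) {
    stop_validation(sprintf(
      "band '%s': low_hz (%g) must be < high_hz (%g)", name, low_hz, high_hz
    ))
  }
  data.frame(name = name, low_hz = low_hz, high_hz = high_hz,
             stringsAsFactors = FALSE)
}

validate_bands <- function(bands) {
  if (!is.data.frame(bands) ||
      !all(c("name", "low_hz", "high_hz") %in% names(bands))) {
    stop_validation("'bands' must be a data frame with name/low_hz/high_hz")
  }
  if (any(bands$low_hz >= bands$high_hz)) {
    stop_validation("every band must satisfy low_hz < high_hz")
  }
  o <- order(bands$low_hz)
  b <- bands[o, ]
  if (nrow(b) > 1L && any(b$low_hz[-1L] < b$high_hz[-nrow(b)])) {
    stop_validation("bands must be non-overlapping")
  }
  b
}
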