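# Segmentation of a recording into overlapping fixed-length analysis frames.
# The defaults (2 s frames, 1 s overlap) are the framing the downstream
# feature extractor is designed for.

#' Segment a recording into overlapping frames
#'
#' Frames are laid left-to-right from sample 1 with step
#' `frame_length_s - overlap_s`; trailing samples that do not fill a whole
#' frame are dropped so every frame has identical length and comparable
#' spectral resolution. Indexing is half-open: frame i covers samples
#' `[(i-1)*step + 1, (i-1)*step + frame_samples]`.
#'
#' No filtering, re-referencing or artifact rejection is applied; pass a
#' `preprocess` function operating on the signal matrix if your data needs
#' any.
#'
#' @param recording A `ctesm_recording`.
#' @param frame_length_s Frame length in seconds (default 2).
#' @param overlap_s Overlap between consecutive frames in seconds (default
#'   1); must be smaller than `frame_length_s`.
#' @param preprocess Optional function `signal_matrix -> signal_matrix`
#'   applied before windowing (pass-through hook; default identity).
#' @return A `ctesm_frameset`: list with `frames` (list of
#'   frame_samples x n_channels matrices), framing parameters, sampling
#'   rate, `subject_id` and `label`.
#' @export
#' @examples
#' rec <- generate_cohort(cohort_spec(n_subjects_per_class = 1,
#'   n_channels = 2, sampling_rate_hz = 128, duration_s = 10, seed = 1))[[1]]
#' fs <- window_frames(rec)
#' length(fs$frames)  # floor((1280 - 256) / 128) + 1 = 9
window_frames <- function(recording, frame_length_s = 2, overlap_s = 1,
                          preprocess = NULL) {
  if (!inherits(recording, "ctesm_recording")) {
    stop_validation("'recording' must be a ctesm_recording")
  }
  check_positive_scalar(frame_length_s, "frame_length_s")
  check_positive_scalar(overlap_s, "overlap_s", allow_zero = TRUE)
  if (overlap_s >= frame_length_s) {
    stop_validation(sprintf(
      "overlap_s (%g) must be smaller than frame_length_s (%g)",
      overlap_s, frame_length_s))
  }
  sig <- recording$signal
  if (!is.null(preprocess)) sig <- preprocess(sig)
  fs <- recording$sampling_rate_hz
  frame_samples <- round(frame_length_s * fs)
  step <- round((frame_length_s - overlap_s) * fs)
  n <- nrow(sig)
  if (n < frame_samples) {
    stop_validation(sprintf(
      "recording duration (%g s) shorter than frame length (%g s)",
      n / fs, frame_length_s))
  }
  n_frames <- floor((n - frame_samples) / step) + 1L
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    start <- (i - 1L) * step
    frames[[i]] <- sig[(start + 1L):(start + frame_samples), , drop = FALSE]
  }
  structure(
    list(frames = frames, frame_length_s = frame_length_s,
         overlap_s = overlap_s, sampling_rate_hz = fs,
         subject_id = recording$subject_id, label = recording$label),
    class = "ctesm_frameset"
  )
}

#' @export
print.ctesm_frameset <- function(x, ...) {
  cat(sprintf(
    "<ctesm_frameset> %s [%s]: %d frames of %d samples x %d channels\n",
    x$subject_id, x$label, length(x$frames), nrow(x$frames[[1]]),
    ncol(x$frames[[1]])))
  invisible(x)
}
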