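#' Restore per-sample labels from segment labels
#'
#' With stride-1 windows there is one segment starting at every sample
#' `0 .. n_samples - W`. Under the default centre alignment, sample
#' `j + floor(W / 2)` takes the label of the segment starting at `j` -- a
#' segment's label summarises the window's interior (its training label is
#' the window majority), so assigning it to the window centre keeps phase
#' boundaries unbiased; the `floor(W / 2)` leading and `W - 1 - floor(W / 2)`
#' trailing samples take the first and last segment's label. Start
#' alignment (`alignment = "start"`) instead assigns segment `j`'s label to
#' sample `j`, which shifts every reconstructed boundary about half a
#' window early; it is kept selectable for sensitivity analysis. At
#' `W = 1` both are the identity.
#'
#' @param segment_labels Integer phase codes, one per segment
#'   (`n_samples - W + 1` of them).
#' @param W Window size in samples.
#' @param n_samples Total sample count of the trial.
#' @param fs Sampling rate in Hz.
#' @param alignment `"center"` (default) or `"start"`.
#' @return A [phase_label_sequence()] of length `n_samples`.
#' @export
segments_to_samples <- function(segment_labels, W, n_samples, fs = 128,
                                alignment = c("center", "start")) {
  alignment <- match.arg(alignment)
  segment_labels <- check_phase_codes(segment_labels)
  W <- as.integer(W)
  n_samples <- as.integer(n_samples)
  n_seg <- length(segment_labels)
  if (n_seg != n_samples - W + 1L) {
    stop("validation error: expected ", n_samples - W + 1L,
         " segment labels, got ", n_seg, call. = FALSE)
  }
  labels <- if (alignment == "start") {
    c(segment_labels, rep(segment_labels[n_seg], W - 1L))
  } else {
    off <- W %/% 2L
    c(rep(segment_labels[1L], off), segment_labels,
      rep(segment_labels[n_seg], W - 1L - off))
  }
  phase_label_sequence(labels, fs = fs)
}

#' Extract the multiphase information from a sample-label sequence
#'
#' Collapses maximal constant-label runs into a [phase_timeline()]: the
#' starting point, ending point and duration of each identified phase.
#'
#' @param sample_labels A [phase_label_sequence()] (or a bare code vector).
#' @param fs Sampling rate, used when a bare vector is given.
#' @return A [phase_timeline()].
#' @export
extract_phase_info <- function(sample_labels, fs = 128) {
  if (!inherits(sample_labels, "phase_label_sequence")) {
    sample_labels <- phase_label_sequence(sample_labels, fs = fs)
  }
  labels_to_timeline(sample_labels)
}

#' Identify the phases of one trial
#'
#' The full identification path for a single stream: stride-1 windowing,
#' feature extraction, phase classification, fragment modification
#' (optional), restoration of the per-sample sequence, and run-length
#' extraction of the phase timeline.
#'
#' @param model A fitted `multiphase_model`.
#' @param stream An [imu_stream()].
#' @param W Window size in samples.
#' @param fragment_fix Apply [modify_fragments()] to the segment
#'   predictions (default `TRUE`).
#' @param alignment Segment-to-sample alignment mode, see
#'   [segments_to_samples()].
#' @return A list with `segment_labels` (raw predictions), `sample_labels`
#'   (a [phase_label_sequence()]) and `timeline` (a [phase_timeline()]).
#' @export
identify_trial <- function(model, stream, W, fragment_fix = TRUE,
                           alignment = "center") {
  stopifnot(inherits(model, "multiphase_model"),
            inherits(stream, "imu_stream"))
  feats <- extract_feature_matrix(stream, W)
  seg_pred <- predict(model, feats)
  seg_out <- if (fragment_fix) modify_fragments(seg_pred) else seg_pred
  samp <- segments_to_samples(seg_out, W, stream$n_samples, fs = stream$fs,
                              alignment = alignment)
  list(segment_labels = seg_pred,
       modified_labels = seg_out,
       sample_labels = samp,
       timeline = extract_phase_info(samp))
}
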