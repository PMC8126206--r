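#' Sliding-window segmentation
#'
#' Divides a stream into overlapping segments of `W` samples advanced one
#' sample at a time, giving `n_samples - W + 1` segments. Window sizes of
#' 8, 16, 24, 32 and 40 samples (0.0625--0.3125 s at 128 Hz) are the ones
#' studied for this pipeline; other positive sizes are accepted with a
#' warning.
#'
#' @param stream An [imu_stream()], or an integer sample count.
#' @param W Window size in samples.
#' @return An object of class `segment_sequence`: list with `W`, `stride`
#'   (always 1), `start_indices` (0-based) and `n_segments`.
#' @export
slide_windows <- function(stream, W) {
  n <- if (inherits(stream, "imu_stream")) stream$n_samples
       else as.integer(stream)
  W <- as.integer(W)
  if (is.na(W) || W < 1L) stop("window size must be a positive integer",
                               call. = FALSE)
  if (!W %in% c(8L, 16L, 24L, 32L, 40L)) {
    warning("window size ", W, " is outside the studied set {8,16,24,32,40}")
  }
  if (n < W) {
    stop("stream-too-short: ", n, " samples < window of ", W, call. = FALSE)
  }
  structure(list(W = W, stride = 1L,
                 start_indices = 0:(n - W),
                 n_segments = n - W + 1L),
            class = "segment_sequence")
}

#' Resultant magnitude of a tri-axial signal
#'
#' Per-sample Euclidean magnitude `sqrt(x^2 + y^2 + z^2)`, used to form the
#' acceleration resultant A_R and the angular-velocity resultant G_R.
#'
#' @param x,y,z Numeric vectors of equal length.
#' @return Numeric vector of magnitudes.
#' @examples
#' resultant(0, 0, 1)      # 1
#' resultant(0.6, 0.8, 0)  # 1
#' @export
resultant <- function(x, y, z) {
  sqrt(x^2 + y^2 + z^2)
}

feature_channel_names <- function() {
  c("ax", "ay", "az", "gx", "gy", "gz", "a_r", "g_r")
}

feature_stat_names <- function() {
  c("mean", "std", "var", "max", "min", "range", "kurtosis", "skewness")
}

#' @rdname extract_feature_matrix
#' @return `feature_names()`: the 64 column names, channel-major
#'   (`ax_mean`, `ax_std`, ..., `g_r_skewness`).
#' @export
feature_names <- function() {
  as.vector(t(outer(feature_channel_names(), feature_stat_names(),
                    paste, sep = "_")))
}

signal_matrix8 <- function(stream) {
  cbind(stream_matrix(stream),
        a_r = resultant(stream$ax, stream$ay, stream$az),
        g_r = resultant(stream$gx, stream$gy, stream$gz))
}

#' Sliding-window feature extraction
#'
#' Computes the 64-dimensional statistical feature vector of every window:
#' eight statistics (mean, std, var, max, min, range, kurtosis, skewness)
#' of each of eight signals (ax, ay, az, gx, gy, gz and the resultants A_R,
#' G_R). Variance is the population (1/n) estimator with `std = sqrt(var)`;
#' kurtosis and skewness are the uncorrected moment estimators, kurtosis on
#' the normal-baseline-3 convention. On a constant window std, var and
#' range are 0 and kurtosis and skewness are defined as 0, so downstream
#' classifiers never see non-finite inputs.
#'
#' @param stream An [imu_stream()].
#' @param W Window size in samples.
#' @param starts Optional 0-based window start indices to keep (default:
#'   every window, stride 1).
#' @return `extract_feature_matrix()`: a numeric matrix with one row per
#'   window and the 64 columns of [feature_names()], plus an attribute
#'   `starts` with the 0-based window starts.
#' @export
extract_feature_matrix <- function(stream, W, starts = NULL) {
  stopifnot(inherits(stream, "imu_stream"))
  seg <- slide_windows(stream, W)
  feats <- sliding_stats_cpp(signal_matrix8(stream), seg$W)
  colnames(feats) <- feature_names()
  keep <- seg$start_indices
  if (!is.null(starts)) {
    starts <- as.integer(starts)
    if (any(starts < 0L | starts > stream$n_samples - W)) {
      stop("window start indices out of range", call. = FALSE)
    }
    feats <- feats[starts + 1L, , drop = FALSE]
    keep <- starts
  }
  attr(feats, "starts") <- keep
  feats
}

#' @rdname extract_feature_matrix
#' @param start 0-based start index of a single window.
#' @return `extract_features()`: a named numeric vector of length 64 for
#'   the window starting at `start`.
#' @export
extract_features <- function(stream, W, start = 0L) {
  m <- extract_feature_matrix(stream, W, starts = start)
  m[1L, ]
}

#' Export a feature matrix as CSV
#'
#' Writes the 64 feature columns plus `segment_start` (0-based window
#' start) and, when labels are supplied, a `label` column.
#'
#' @param feats A matrix from [extract_feature_matrix()].
#' @param path Output CSV path.
#' @param labels Optional segment label codes (one per row).
#' @return Invisibly, `path`.
#' @export
write_features_csv <- function(feats, path, labels = NULL) {
  df <- as.data.frame(feats)
  df$segment_start <- attr(feats, "starts")
  if (!is.null(labels)) {
    if (length(labels) != nrow(df)) {
      stop("validation error: one label per feature row required",
           call. = FALSE)
    }
    df$label <- check_phase_codes(labels)
  }
  data.table::fwrite(df, path)
  invisible(path)
}

#' Ground-truth labels for segments
#'
#' Assigns each window the majority per-sample label inside it. Ties are
#' broken toward the earlier phase in canonical order (the lower code).
#'
#' @param truth A [phase_label_sequence()].
#' @param segments A `segment_sequence` from [slide_windows()], or a window
#'   size `W`.
#' @param starts Optional subset of 0-based window starts.
#' @return Integer vector of phase codes, one per (kept) segment.
#' @export
label_segments <- function(truth, segments, starts = NULL) {
  stopifnot(inherits(truth, "phase_label_sequence"))
  if (!inherits(segments, "segment_sequence")) {
    segments <- slide_windows(length(truth$labels), segments)
  }
  n <- length(truth$labels)
  W <- segments$W
  if (n < W + segments$start_indices[length(segments$start_indices)]) {
    stop("truth sequence shorter than segment coverage", call. = FALSE)
  }
  # cumulative per-class counts -> windowed counts, then first-max tie rule
  idx <- W:n  # 1-based window ends
  counts <- vapply(0:6, function(cl) {
    cs <- cumsum(truth$labels == cl)
    cs[idx] - c(0, cs)[idx - W + 1L]
  }, numeric(n - W + 1L))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  lab <- max.col(counts, ties.method = "first") - 1L
  if (!is.null(starts)) lab <- lab[as.integer(starts) + 1L]
  as.integer(lab)
}
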