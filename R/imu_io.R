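#' Construct an IMU stream
#'
#' A fixed-rate six-channel inertial time series for one trial: tri-axial
#' acceleration in g (`ax`, `ay`, `az`) and tri-axial angular velocity in
#' deg/s (`gx`, `gy`, `gz`), sampled at `fs` Hz. Sample indexing is 0-based
#' throughout the package.
#'
#' @param ax,ay,az Numeric acceleration channels (g).
#' @param gx,gy,gz Numeric angular-velocity channels (deg/s).
#' @param fs Sampling rate in Hz (default 128).
#' @return An object of class `imu_stream`: a list with the six channels,
#'   `fs` and `n_samples`.
#' @export
imu_stream <- function(ax, ay, az, gx, gy, gz, fs = 128) {
  chans <- list(ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
                gx = as.numeric(gx), gy = as.numeric(gy), gz = as.numeric(gz))
  n <- length(chans$ax)
  lens <- vapply(chans, length, integer(1))
  if (any(lens != n)) {
    stop("malformed-stream: channel lengths differ (",
         paste(lens, collapse = ", "), ")", call. = FALSE)
  }
  if (n < 1L) stop("malformed-stream: empty stream", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("malformed-stream: fs must be a single positive number", call. = FALSE)
  }
  if (!all(vapply(chans, function(x) all(is.finite(x)), logical(1)))) {
    stop("malformed-stream: non-finite values in channels", call. = FALSE)
  }
  structure(c(chans, list(fs = as.numeric(fs), n_samples = n)),
            class = "imu_stream")
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> %d samples @ %g Hz (%.3f s)\n",
              x$n_samples, x$fs, x$n_samples / x$fs))
  invisible(x)
}

stream_matrix <- function(stream) {
  cbind(ax = stream$ax, ay = stream$ay, az = stream$az,
        gx = stream$gx, gy = stream$gy, gz = stream$gz)
}

#' Per-sample phase label sequence
#'
#' @param labels Integer vector of phase codes (0--6), one per sample.
#' @param fs Sampling rate in Hz.
#' @return An object of class `phase_label_sequence`.
#' @export
phase_label_sequence <- function(labels, fs = 128) {
  labels <- check_phase_codes(labels)
  if (length(labels) < 1L) stop("empty label sequence", call. = FALSE)
  structure(list(labels = labels, fs = as.numeric(fs)),
            class = "phase_label_sequence")
}

#' Phase timeline
#'
#' An ordered set of contiguous, non-overlapping phase intervals covering a
#' trial. Intervals are closed `[start_sample, end_sample]` with 0-based
#' sample indices, so `duration_s = (end - start + 1) / fs`. Adjacent
#' intervals must carry distinct phases.
#'
#' @param phase Integer phase codes, one per interval.
#' @param start_sample,end_sample 0-based inclusive sample bounds.
#' @param fs Sampling rate in Hz.
#' @return An object of class `phase_timeline`: a data.frame with columns
#'   `phase`, `start_sample`, `end_sample`, `duration_s`.
#' @export
phase_timeline <- function(phase, start_sample, end_sample, fs = 128) {
  phase <- check_phase_codes(phase)
  start_sample <- as.integer(start_sample)
  end_sample <- as.integer(end_sample)
  k <- length(phase)
  if (length(start_sample) != k || length(end_sample) != k || k < 1L) {
    stop("malformed-labels: interval columns must have equal positive length",
         call. = FALSE)
  }
  ord <- order(start_sample)
  phase <- phase[ord]; start_sample <- start_sample[ord]
  end_sample <- end_sample[ord]
  if (any(end_sample < start_sample)) {
    stop("malformed-labels: interval with end before start", call. = FALSE)
  }
  if (start_sample[1L] != 0L) {
    stop("malformed-labels: first interval must start at sample 0",
         call. = FALSE)
  }
  if (k > 1L) {
    gaps <- start_sample[-1L] - end_sample[-k] - 1L
    if (any(gaps > 0L)) {
      stop("malformed-labels: gap between intervals", call. = FALSE)
    }
    if (any(gaps < 0L)) {
      stop("malformed-labels: overlapping intervals", call. = FALSE)
    }
    if (any(phase[-1L] == phase[-k])) {
      stop("malformed-labels: adjacent intervals share a phase", call. = FALSE)
    }
  }
  out <- data.frame(phase = phase,
                    start_sample = start_sample,
                    end_sample = end_sample,
                    duration_s = (end_sample - start_sample + 1L) / fs)
  attr(out, "fs") <- as.numeric(fs)
  class(out) <- c("phase_timeline", "data.frame")
  out
}

#' Convert a per-sample label sequence to a phase timeline and back
#'
#' `labels_to_timeline()` collapses maximal constant-label runs into closed
#' intervals; `timeline_to_labels()` expands intervals back to one code per
#' sample. The two are inverse bijections for contiguous sequences.
#'
#' @param seq A [phase_label_sequence()].
#' @return A [phase_timeline()].
#' @export
labels_to_timeline <- function(seq) {
  stopifnot(inherits(seq, "phase_label_sequence"))
  r <- rle(seq$labels)
  ends <- cumsum(r$lengths)
  phase_timeline(phase = r$values,
                 start_sample = ends - r$lengths,
                 end_sample = ends - 1L,
                 fs = seq$fs)
}

#' @rdname labels_to_timeline
#' @param timeline A [phase_timeline()].
#' @param fs Sampling rate; defaults to the timeline's own.
#' @return `timeline_to_labels()`: a [phase_label_sequence()].
#' @export
timeline_to_labels <- function(timeline, fs = attr(timeline, "fs")) {
  stopifnot(inherits(timeline, "phase_timeline"))
  lens <- timeline$end_sample - timeline$start_sample + 1L
  phase_label_sequence(rep(timeline$phase, lens), fs = fs)
}

#' Trial record
#'
#' One protocol trial: metadata (subject, fall type, direction, repetition),
#' the sensor stream and its ground-truth per-sample labels.
#'
#' @param stream An [imu_stream()].
#' @param truth A [phase_label_sequence()] of the same length.
#' @param subject_id Subject identifier (integer).
#' @param fall_type Fall type 1--7 (see [fall_protocol()]).
#' @param direction One of `"forward"`, `"backward"`, `"right-lateral"`,
#'   `"left-lateral"`.
#' @param repetition Repetition number (1--3 in the standard protocol).
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(stream, truth, subject_id = NA_integer_,
                         fall_type = NA_integer_, direction = NA_character_,
                         repetition = NA_integer_) {
  stopifnot(inherits(stream, "imu_stream"),
            inherits(truth, "phase_label_sequence"))
  if (length(truth$labels) != stream$n_samples) {
    stop("malformed-labels: label sequence length (", length(truth$labels),
         ") != stream length (", stream$n_samples, ")", call. = FALSE)
  }
  if (!is.na(fall_type)) check_type_direction(fall_type, direction)
  structure(list(subject_id = as.integer(subject_id),
                 fall_type = as.integer(fall_type),
                 direction = as.character(direction),
                 repetition = as.integer(repetition),
                 stream = stream, truth = truth),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> subject %s, type %s (%s), rep %s: %d samples @ %g Hz\n",
              x$subject_id, x$fall_type, x$direction, x$repetition,
              x$stream$n_samples, x$stream$fs))
  invisible(x)
}

#' Read a trial from its stream and label CSV files
#'
#' The stream CSV has header `time,ax,ay,az,gx,gy,gz` (time in seconds,
#' acceleration in g, angular velocity in deg/s). The label CSV is either a
#' timeline (`phase,start_sample,end_sample`, phase names from
#' [phase_names()]) or per-sample (`sample,code`). Label intervals must
#' cover every sample exactly once.
#'
#' @param stream_path,labels_path Paths to the two CSV files.
#' @param fs Sampling rate in Hz; taken from configuration rather than
#'   inferred from timestamps.
#' @param subject_id,fall_type,direction,repetition Optional metadata.
#' @return A [trial_record()].
#' @export
read_trial <- function(stream_path, labels_path, fs = 128,
                       subject_id = NA_integer_, fall_type = NA_integer_,
                       direction = NA_character_, repetition = NA_integer_) {
  sdt <- data.table::fread(stream_path, data.table = FALSE)
  need <- c("time", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(sdt))) {
    stop("malformed-stream: expected header time,ax,ay,az,gx,gy,gz in ",
         stream_path, call. = FALSE)
  }
  stream <- imu_stream(sdt$ax, sdt$ay, sdt$az, sdt$gx, sdt$gy, sdt$gz, fs = fs)

  truth <- read_labels_csv(labels_path, fs = fs)
  if (length(truth$labels) != stream$n_samples) {
    stop("malformed-labels: labels cover ", length(truth$labels),
         " samples but stream has ", stream$n_samples, call. = FALSE)
  }
  trial_record(stream, truth, subject_id = subject_id, fall_type = fall_type,
               direction = direction, repetition = repetition)
}

#' Read a phase-label CSV
#'
#' Accepts either the timeline dialect (`phase,start_sample,end_sample`,
#' phase as a name or code) or the per-sample dialect (`sample,code`).
#'
#' @param labels_path Path to the CSV file.
#' @param fs Sampling rate in Hz.
#' @return A [phase_label_sequence()].
#' @export
read_labels_csv <- function(labels_path, fs = 128) {
  ldt <- data.table::fread(labels_path, data.table = FALSE)
  if (all(c("phase", "start_sample", "end_sample") %in% names(ldt))) {
    codes <- if (is.character(ldt$phase)) phase_code(ldt$phase)
             else check_phase_codes(ldt$phase)
    tl <- phase_timeline(codes, ldt$start_sample, ldt$end_sample, fs = fs)
    timeline_to_labels(tl, fs = fs)
  } else if (all(c("sample", "code") %in% names(ldt))) {
    ord <- order(ldt$sample)
    if (!identical(as.integer(ldt$sample[ord]),
                   seq_len(nrow(ldt)) - 1L)) {
      stop("malformed-labels: per-sample rows must cover 0..n-1 exactly once",
           call. = FALSE)
    }
    phase_label_sequence(ldt$code[ord], fs = fs)
  } else {
    stop("malformed-labels: expected header phase,start_sample,end_sample ",
         "or sample,code in ", labels_path, call. = FALSE)
  }
}

#' Write a trial to stream and label CSV files
#'
#' Emits the dialect read by [read_trial()]: the stream as
#' `time,ax,ay,az,gx,gy,gz` and the ground truth as a timeline
#' `phase,start_sample,end_sample` sorted by start sample.
#'
#' @param trial A [trial_record()].
#' @param stream_path,labels_path Output paths.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_trial <- function(trial, stream_path, labels_path) {
  stopifnot(inherits(trial, "trial_record"))
  s <- trial$stream
  n <- s$n_samples
  sdt <- data.frame(time = (seq_len(n) - 1L) / s$fs,
                    ax = s$ax, ay = s$ay, az = s$az,
                    gx = s$gx, gy = s$gy, gz = s$gz)
  tl <- labels_to_timeline(trial$truth)
  ldt <- data.frame(phase = phase_name(tl$phase),
                    start_sample = tl$start_sample,
                    end_sample = tl$end_sample)
  ok1 <- try(data.table::fwrite(sdt, stream_path), silent = TRUE)
  ok2 <- try(data.table::fwrite(ldt, labels_path), silent = TRUE)
  if (inherits(ok1, "try-error") || inherits(ok2, "try-error")) {
    stop("I/O error writing trial CSVs", call. = FALSE)
  }
  invisible(c(stream = stream_path, labels = labels_path))
}
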