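#' Sample-based confusion counts for one phase
#'
#' One-versus-rest counts from the sample-by-sample mapping between the
#' identified sequence and the ground truth: the target phase is
#' "positive", every other phase "negative". TP + FP + TN + FN equals the
#' number of samples.
#'
#' @param pred,truth [phase_label_sequence()] objects (or bare code
#'   vectors) of equal length.
#' @param phase Target phase code (0--6).
#' @return A named integer vector with elements `TP`, `FP`, `TN`, `FN`.
#' @export
count_confusion <- function(pred, truth, phase) {
  p <- if (inherits(pred, "phase_label_sequence")) pred$labels
       else check_phase_codes(pred)
  g <- if (inherits(truth, "phase_label_sequence")) truth$labels
       else check_phase_codes(truth)
  if (length(p) != length(g)) {
    stop("validation error: prediction and truth lengths differ",
         call. = FALSE)
  }
  check_phase_codes(phase)
  pp <- p == phase
  gp <- g == phase
  c(TP = sum(pp & gp), FP = sum(pp & !gp),
    TN = sum(!pp & !gp), FN = sum(!pp & gp))
}

confusion_all_phases <- function(pred, truth) {
  t(vapply(0:6, function(ph) count_confusion(pred, truth, ph), integer(4)))
}

#' Evaluation metrics from confusion counts
#'
#' Computes, as percentages: sensitivity `TP / (TP + FN)`, precision
#' `TP / (TP + FP)`, Jaccard coefficient `TP / (TP + FP + FN)` and
#' accuracy `(TP + TN) / (TP + FP + TN + FN)`.
#'
#' 0/0 conventions: a phase absent from both truth and prediction scores
#' 100 on sensitivity, precision and Jaccard (vacuous agreement); a phase
#' absent from the truth but predicted has undefined sensitivity (`NA`,
#' excluded from averages); a phase present in the truth but never
#' predicted has undefined precision (`NA`).
#'
#' @param counts A named vector with `TP`, `FP`, `TN`, `FN`, or a 7 x 4
#'   matrix of per-phase counts (rows = phases 0--6).
#' @return For a single count vector, a named numeric vector `sensitivity`,
#'   `precision`, `jaccard`, `accuracy` (percent). For a matrix, a
#'   data.frame with one row per phase.
#' @export
compute_metrics <- function(counts) {
  if (is.matrix(counts)) {
    out <- as.data.frame(t(apply(counts, 1, compute_metrics)))
    out <- cbind(phase = 0:6, phase_name = phase_name(0:6), out)
    rownames(out) <- NULL
    return(out)
  }
  if (any(counts < 0)) stop("validation error: negative counts", call. = FALSE)
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  ratio <- function(num, den, vacuous) {
    if (den == 0) vacuous else 100 * num / den
  }
  absent_everywhere <- (tp + fn == 0) && (tp + fp == 0)
  c(sensitivity = ratio(tp, tp + fn, if (absent_everywhere) 100 else NA_real_),
    precision = ratio(tp, tp + fp, if (absent_everywhere) 100 else NA_real_),
    jaccard = ratio(tp, tp + fp + fn, 100),
    accuracy = ratio(tp + tn, tp + fp + tn + fn, NA_real_))
}

#' Leave-one-subject-out fold composition
#'
#' @param dataset A `fall_dataset`.
#' @return A list with one element per subject: `subject`, `train_idx`,
#'   `test_idx` (indices into `dataset$trials`).
#' @export
losocv_folds <- function(dataset) {
  stopifnot(inherits(dataset, "fall_dataset"))
  subs <- vapply(dataset$trials, function(tr) tr$subject_id, integer(1))
  lapply(sort(unique(subs)), function(s) {
    test_idx <- which(subs == s)
    if (length(test_idx) == 0L) {
      stop("fold-composition error: subject ", s, " has no trials",
           call. = FALSE)
    }
    list(subject = s, train_idx = which(subs != s), test_idx = test_idx)
  })
}

#' Leave-one-subject-out cross-validation of the identification pipeline
#'
#' For each fold, trains the classifier on every other subject's segment
#' features and majority labels, then runs the full identification path on
#' each held-out trial (stride-1 prediction, fragment modification,
#' sample restoration) and scores it sample-by-sample against the ground
#' truth. Training windows may be subsampled with `train_stride` (default:
#' one window per window length, i.e. non-overlapping training windows);
#' test trials are always predicted at stride 1.
#'
#' @param dataset A `fall_dataset` with at least two subjects.
#' @param spec A [classifier_spec()].
#' @param W Window size in samples.
#' @param train_stride Stride (samples) between training windows.
#' @param fragment_fix Apply fragment modification before scoring
#'   (default `TRUE`); set `FALSE` for ablation of the rule pass.
#' @param score_segments Score raw segment predictions against majority
#'   segment labels instead of the restored sample sequence.
#' @param alignment Segment-to-sample alignment, see
#'   [segments_to_samples()].
#' @return An object of class `eval_report`: list with `folds` (per-fold
#'   pooled counts and metrics), `per_phase` (fold-averaged per-phase
#'   metrics), `pooled` (metrics from counts pooled over all folds),
#'   `overall` (macro-averaged sensitivity/precision/Jaccard and micro
#'   accuracy), and the configuration used.
#' @export
run_losocv <- function(dataset, spec = classifier_spec(), W = 24L,
                       train_stride = W, fragment_fix = TRUE,
                       score_segments = FALSE, alignment = "center") {
  stopifnot(inherits(dataset, "fall_dataset"))
  folds <- losocv_folds(dataset)
  if (length(folds) < 2L) {
    stop("fold-composition error: LOSOCV needs >= 2 subjects", call. = FALSE)
  }
  W <- as.integer(W)

  # training windows (subsampled) are reused across folds
  train_cache <- lapply(dataset$trials, function(tr) {
    starts <- seq.int(0L, tr$stream$n_samples - W, by = as.integer(train_stride))
    list(x = extract_feature_matrix(tr$stream, W, starts = starts),
         y = label_segments(tr$truth, W, starts = starts))
  })

  fold_results <- lapply(folds, function(fold) {
    xtr <- do.call(rbind, lapply(train_cache[fold$train_idx], `[[`, "x"))
    ytr <- unlist(lapply(train_cache[fold$train_idx], `[[`, "y"))
    model <- fit_multiphase(xtr, ytr, spec)

    counts <- matrix(0L, 7L, 4L, dimnames = list(phase_name(0:6),
                                                 c("TP", "FP", "TN", "FN")))
    correct <- 0L
    total <- 0L
    for (ti in fold$test_idx) {
      tr <- dataset$trials[[ti]]
      res <- identify_trial(model, tr$stream, W, fragment_fix = fragment_fix,
                            alignment = alignment)
      if (score_segments) {
        pred <- if (fragment_fix) res$modified_labels else res$segment_labels
        truth <- label_segments(tr$truth, W)
      } else {
        pred <- res$sample_labels$labels
        truth <- tr$truth$labels
      }
      counts <- counts + confusion_all_phases(pred, truth)
      correct <- correct + sum(pred == truth)
      total <- total + length(truth)
    }
    metrics <- compute_metrics(counts)
    list(subject = fold$subject, counts = counts, metrics = metrics,
         micro_accuracy = 100 * correct / total,
         n_train = length(fold$train_idx), n_test = length(fold$test_idx))
  })

  metric_cols <- c("sensitivity", "precision", "jaccard", "accuracy")
  per_phase <- fold_results[[1]]$metrics[, c("phase", "phase_name")]
  for (mc in metric_cols) {
    m <- vapply(fold_results, function(fr) fr$metrics[[mc]],
                numeric(7))
    per_phase[[mc]] <- rowMeans(m, na.rm = TRUE)
  }
  pooled_counts <- Reduce(`+`, lapply(fold_results, `[[`, "counts"))
  pooled <- compute_metrics(pooled_counts)
  micro <- vapply(fold_results, `[[`, numeric(1), "micro_accuracy")

  overall <- c(sensitivity = mean(per_phase$sensitivity),
               precision = mean(per_phase$precision),
               jaccard = mean(per_phase$jaccard),
               accuracy = mean(micro),
               accuracy_per_class_mean = mean(per_phase$accuracy))

  structure(list(folds = fold_results, per_phase = per_phase,
                 pooled = pooled, pooled_counts = pooled_counts,
                 overall = overall,
                 config = list(technique = spec$technique, W = W,
                               train_stride = train_stride,
                               fragment_fix = fragment_fix,
                               score_segments = score_segments,
                               alignment = alignment,
                               spec = unclass(spec))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, W=%d, %d folds\n",
              x$config$technique, x$config$W, length(x$folds)))
  cat(sprintf("overall: sensitivity %.2f%%, precision %.2f%%, Jaccard %.2f%%, accuracy %.2f%%\n",
              x$overall[["sensitivity"]], x$overall[["precision"]],
              x$overall[["jaccard"]], x$overall[["accuracy"]]))
  print(x$per_phase, digits = 4)
  invisible(x)
}

#' Flatten an evaluation report to data frames
#'
#' @param report An `eval_report`.
#' @return A list of two data.frames: `summary` (one row per metric) and
#'   `per_phase` (fold-averaged per-phase metrics).
#' @export
report_tables <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  list(summary = data.frame(metric = names(report$overall),
                            value = as.numeric(report$overall)),
       per_phase = report$per_phase)
}
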