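test_that("confusion counts follow the one-vs-rest sample mapping", {
  truth <- c(rep(3L, 10), rep(4L, 90))
  pred <- c(rep(3L, 8), 4L, 4L, rep(3L, 2), rep(4L, 88))
  counts <- count_confusion(pred, truth, 3L)
  expect_equal(counts, c(TP = 8L, FP = 2L, TN = 88L, FN = 2L))
  expect_equal(sum(counts), length(truth))
  # identical sequences have no errors anywhere
  for (ph in 0:6) {
    c0 <- count_confusion(truth, truth, ph)
    expect_equal(c0[["FP"]], 0L)
    expect_equal(c0[["FN"]], 0L)
    expect_equal(sum(c0), length(truth))
  }
  expect_error(count_confusion(1:5, 1:6, 1L), "lengths differ")
})

test_that("metrics reproduce hand arithmetic", {
  m <- compute_metrics(c(TP = 8, FP = 2, TN = 88, FN = 2))
  expect_equal(m[["sensitivity"]], 80)
  expect_equal(m[["precision"]], 80)
  expect_equal(m[["jaccard"]], 100 * 8 / 12, tolerance = 1e-12)
  expect_equal(round(m[["jaccard"]], 2), 66.67)
  expect_equal(m[["accuracy"]], 96)
  expect_equal(compute_metrics(c(TP = 0, FP = 0, TN = 90, FN = 10))[["sensitivity"]], 0)
})

test_that("0/0 conventions distinguish vacuous from spurious phases", {
  # absent from truth and prediction: vacuous agreement
  m <- compute_metrics(c(TP = 0, FP = 0, TN = 100, FN = 0))
  expect_equal(m[["sensitivity"]], 100)
  expect_equal(m[["precision"]], 100)
  expect_equal(m[["jaccard"]], 100)
  # absent from truth but predicted: sensitivity undefined
  m <- compute_metrics(c(TP = 0, FP = 5, TN = 95, FN = 0))
  expect_true(is.na(m[["sensitivity"]]))
  expect_equal(m[["precision"]], 0)
  # present in truth, never predicted: precision undefined
  m <- compute_metrics(c(TP = 0, FP = 0, TN = 95, FN = 5))
  expect_true(is.na(m[["precision"]]))
  expect_equal(m[["sensitivity"]], 0)
})

test_that("Jaccard relates to sensitivity and precision algebraically", {
  set.seed(50)
  for (rep_i in 1:50) {
    counts <- c(TP = sample(1:100, 1), FP = sample(0:50, 1),
                TN = sample(0:100, 1), FN = sample(0:50, 1))
    m <- compute_metrics(counts)
    s <- m[["sensitivity"]] / 100
    p <- m[["precision"]] / 100
    j <- m[["jaccard"]] / 100
    expect_equal(j, s * p / (s + p - s * p), tolerance = 1e-12)
    expect_lte(j, min(s, p) + 1e-12)
  }
})

test_that("fold composition leaves one subject out", {
  ds <- generate_protocol_dataset(3, seed = 21, repetitions = 1)
  folds <- losocv_folds(ds)
  expect_length(folds, 3L)
  for (f in folds) {
    expect_length(f$test_idx, 25L)
    expect_length(f$train_idx, 50L)
    subs <- vapply(ds$trials[f$test_idx], `[[`, integer(1), "subject_id")
    expect_true(all(subs == f$subject))
    expect_length(intersect(f$train_idx, f$test_idx), 0L)
  }
  expect_error(run_losocv(generate_protocol_dataset(1, seed = 2,
                                                    repetitions = 1)),
               "2 subjects")
})

test_that("a ground-truth predictor scores 100 on every metric", {
  tr <- make_tiny_trial(c(30, 30, 10, 10, 30, 30, 30))
  truth <- tr$truth$labels
  # the scoring path: segment labels -> sample restoration -> counts
  seg <- suppressWarnings(label_segments(tr$truth, 1L))
  restored <- segments_to_samples(seg, 1L, length(truth))
  counts <- fallphase:::confusion_all_phases(restored$labels, truth)
  m <- compute_metrics(counts)
  expect_true(all(m$sensitivity == 100))
  expect_true(all(m$precision == 100))
  expect_true(all(m$jaccard == 100))
  expect_true(all(m$accuracy == 100))
})

test_that("losocv reports consistent pooled and per-fold counts", {
  ds <- generate_protocol_dataset(2, seed = 33, repetitions = 1)
  rep <- run_losocv(ds, classifier_spec("dt"), W = 16L, train_stride = 48L)
  expect_length(rep$folds, 2L)
  expect_equal(rep$folds[[1]]$n_train, 25L)
  expect_equal(rep$folds[[1]]$n_test, 25L)
  # pooled counts are the sum of the fold counts
  expect_equal(rep$pooled_counts,
               rep$folds[[1]]$counts + rep$folds[[2]]$counts)
  # every phase's counts partition the fold's samples
  n1 <- sum(vapply(ds$trials[losocv_folds(ds)[[1]]$test_idx],
                   function(tr) tr$stream$n_samples, integer(1)))
  expect_true(all(rowSums(rep$folds[[1]]$counts) == n1))
  # metrics are percentages
  pp <- rep$per_phase
  for (mc in c("sensitivity", "precision", "jaccard", "accuracy")) {
    expect_true(all(pp[[mc]] >= 0 & pp[[mc]] <= 100, na.rm = TRUE))
  }
  expect_true(rep$overall[["accuracy"]] > 0 &&
                rep$overall[["accuracy"]] <= 100)
})

test_that("accuracy is invariant under a phase relabelling", {
  set.seed(52)
  truth <- sample(0:6, 500, replace = TRUE)
  pred <- truth
  flip <- sample(500, 60)
  pred[flip] <- (pred[flip] + sample(1:6, 60, replace = TRUE)) %% 7L
  perm <- sample(0:6)
  micro <- function(p, g) mean(p == g)
  expect_equal(micro(perm[pred + 1], perm[truth + 1]), micro(pred, truth))
})
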