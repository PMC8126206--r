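test_that("sliding windows have stride 1 and count n - W + 1", {
  s <- slide_windows(128L, 8L)
  expect_equal(s$n_segments, 121L)
  expect_equal(s$start_indices, 0:120)
  expect_equal(s$stride, 1L)
  expect_equal(slide_windows(8L, 8L)$n_segments, 1L)
  expect_error(slide_windows(7L, 8L), "stream-too-short")
  expect_warning(slide_windows(100L, 10L), "outside the studied set")
  # the largest studied window spans 0.3125 s at 128 Hz
  expect_equal(40 / 128, 0.3125)
})

test_that("resultant is the per-sample Euclidean magnitude", {
  expect_equal(resultant(0, 0, 1), 1)
  expect_equal(resultant(0.6, 0.8, 0), 1)
  set.seed(4)
  x <- rnorm(50); y <- rnorm(50); z <- rnorm(50)
  brute <- vapply(1:50, function(i) sqrt(x[i]^2 + y[i]^2 + z[i]^2),
                  numeric(1))
  expect_equal(resultant(x, y, z), brute)
})

test_that("constant windows give degenerate statistics by convention", {
  n <- 16
  st <- imu_stream(rep(0, n), rep(0, n), rep(1, n),
                   rep(0, n), rep(0, n), rep(0, n))
  f <- extract_features(st, 8L, start = 3L)
  expect_length(f, 64L)
  expect_equal(unname(f["az_mean"]), 1)
  expect_equal(unname(f["a_r_mean"]), 1)
  for (ch in c("ax", "ay", "az", "gx", "gy", "gz", "a_r", "g_r")) {
    for (stat in c("std", "var", "range", "kurtosis", "skewness")) {
      expect_equal(unname(f[paste0(ch, "_", stat)]), 0)
    }
  }
})

test_that("hand-computed window statistics match", {
  st <- imu_stream(c(1, 2, 3, 4), rep(0, 4), rep(1, 4),
                   rep(0, 4), rep(0, 4), rep(0, 4))
  expect_warning(f <- extract_features(st, 4L), "outside the studied set")
  expect_equal(unname(f["ax_mean"]), 2.5)
  expect_equal(unname(f["ax_var"]), 1.25)   # population variance
  expect_equal(unname(f["ax_std"]), sqrt(1.25))
  expect_equal(unname(f["ax_range"]), 3)
  expect_equal(unname(f["ax_max"]), 4)
  expect_equal(unname(f["ax_min"]), 1)
})

test_that("feature extraction matches the naive oracle on random windows", {
  set.seed(77)
  for (rep_i in 1:6) {
    n <- sample(60:200, 1)
    st <- imu_stream(rnorm(n), rnorm(n), rnorm(n, 1),
                     rnorm(n, 0, 30), rnorm(n, 0, 30), rnorm(n, 0, 30))
    W <- sample(c(8L, 16L, 24L, 32L, 40L), 1)
    feats <- extract_feature_matrix(st, W)
    expect_equal(ncol(feats), 64L)
    expect_equal(nrow(feats), n - W + 1L)
    for (start in sample(0:(n - W), 25)) {
      expect_equal(feats[start + 1L, ], feature_oracle(st, W, start),
                   tolerance = 1e-9)
    }
  }
})

test_that("emitted vectors satisfy var = std^2 and range = max - min", {
  set.seed(12)
  n <- 400
  st <- imu_stream(rnorm(n), rnorm(n), rnorm(n, 1),
                   rnorm(n, 0, 50), rnorm(n, 0, 50), rnorm(n, 0, 50))
  feats <- extract_feature_matrix(st, 24L)
  expect_true(all(is.finite(feats)))
  for (ch in c("ax", "ay", "az", "gx", "gy", "gz", "a_r", "g_r")) {
    expect_equal(feats[, paste0(ch, "_var")],
                 feats[, paste0(ch, "_std")]^2, tolerance = 1e-9)
    expect_equal(feats[, paste0(ch, "_range")],
                 feats[, paste0(ch, "_max")] - feats[, paste0(ch, "_min")],
                 tolerance = 1e-9)
  }
})

test_that("features are invariant to permuting samples within the window", {
  set.seed(3)
  W <- 16L
  x <- lapply(1:6, function(i) rnorm(W, 0, i))
  st1 <- do.call(imu_stream, x)
  perm <- sample(W)
  st2 <- do.call(imu_stream, lapply(x, `[`, perm))
  expect_equal(extract_features(st1, W), extract_features(st2, W),
               tolerance = 1e-9)
})

test_that("feature matrices export with starts and labels", {
  set.seed(9)
  n <- 40
  st <- imu_stream(rnorm(n), rnorm(n), rnorm(n, 1),
                   rnorm(n), rnorm(n), rnorm(n))
  feats <- extract_feature_matrix(st, 8L)
  path <- tempfile(fileext = ".csv")
  labs <- sample(0:6, nrow(feats), replace = TRUE)
  write_features_csv(feats, path, labels = labs)
  back <- read.csv(path)
  expect_equal(names(back), c(feature_names(), "segment_start", "label"))
  expect_equal(back$segment_start, 0:(n - 8))
  expect_equal(back$label, labs)
  expect_equal(back$az_mean, unname(feats[, "az_mean"]), tolerance = 1e-12)
  expect_error(write_features_csv(feats, path, labels = labs[-1]),
               "one label per")
})

test_that("segment labels take the window majority with canonical ties", {
  # window entirely inside one phase
  truth <- phase_label_sequence(rep(c(1L, 4L), c(20, 20)))
  labs <- label_segments(truth, 8L)
  expect_equal(labs[1], 1L)
  expect_equal(labs[length(labs)], 4L)
  # 5 impact + 3 resting -> impact
  truth <- phase_label_sequence(c(rep(3L, 5), rep(4L, 5)))
  expect_equal(label_segments(truth, 8L)[1], 3L)
  # 4/4 tie free-fall/impact -> free-fall (earlier canonical phase)
  truth <- phase_label_sequence(c(rep(2L, 4), rep(3L, 8)))
  expect_equal(label_segments(truth, 8L)[1], 2L)
  # tie rule is positional-independent: impact first still yields free-fall
  truth <- phase_label_sequence(c(rep(3L, 4), rep(2L, 8)))
  expect_equal(label_segments(truth, 8L)[1], 2L)
})

test_that("segment labels agree with a naive majority oracle", {
  set.seed(21)
  for (rep_i in 1:10) {
    n <- sample(30:120, 1)
    W <- sample(c(8L, 16L, 24L), 1)
    labs <- random_label_sequence(n)
    truth <- phase_label_sequence(labs)
    got <- label_segments(truth, W)
    want <- vapply(0:(n - W), function(j) {
      tb <- table(factor(labs[(j + 1):(j + W)], levels = 0:6))
      as.integer(names(tb)[which.max(tb)])  # which.max takes first = lowest code
    }, integer(1))
    expect_equal(got, want)
  }
})
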