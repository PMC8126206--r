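test_that("phase vocabulary is a fixed bijection", {
  expect_equal(phase_code(phase_name(0:6)), 0:6)
  expect_equal(phase_name(0L), "initial-static")
  expect_equal(phase_name(6L), "ending-static")
  expect_error(phase_code("sitting"), "unknown phase")
  expect_error(phase_name(7), "0..6")
})

test_that("a minimal stream/labels file pair reads into a trial", {
  sp <- tempfile(fileext = ".csv")
  lp <- tempfile(fileext = ".csv")
  writeLines(c("time,ax,ay,az,gx,gy,gz",
               "0,0,0,1,0,0,0",
               "0.0078125,0,0,1,0,0,0"), sp)
  writeLines(c("phase,start_sample,end_sample",
               "initial-static,0,1"), lp)
  tr <- read_trial(sp, lp, fs = 128)
  expect_s3_class(tr, "trial_record")
  expect_equal(tr$stream$n_samples, 2L)
  expect_equal(tr$truth$labels, c(0L, 0L))
})

test_that("malformed label files are rejected", {
  sp <- tempfile(fileext = ".csv")
  lp <- tempfile(fileext = ".csv")
  n <- 151
  df <- data.frame(time = (0:(n - 1)) / 128, ax = 0, ay = 0, az = 1,
                   gx = 0, gy = 0, gz = 0)
  write.csv(df, sp, row.names = FALSE)
  # overlap at sample 99
  writeLines(c("phase,start_sample,end_sample",
               "initial-static,0,99",
               "pre-fall,99,150"), lp)
  expect_error(read_trial(sp, lp), "overlap")
  # gap
  writeLines(c("phase,start_sample,end_sample",
               "initial-static,0,98",
               "pre-fall,100,150"), lp)
  expect_error(read_trial(sp, lp), "gap")
  # unknown phase name
  writeLines(c("phase,start_sample,end_sample",
               "tumbling,0,150"), lp)
  expect_error(read_trial(sp, lp), "unknown phase")
  # coverage mismatch with the stream
  writeLines(c("phase,start_sample,end_sample",
               "initial-static,0,120"), lp)
  expect_error(read_trial(sp, lp), "malformed-labels")
})

test_that("streams with unequal or non-finite channels are rejected", {
  expect_error(imu_stream(1:3, 1:2, 1:3, 1:3, 1:3, 1:3), "channel lengths")
  expect_error(imu_stream(c(1, NA), c(1, 1), c(1, 1), c(1, 1), c(1, 1),
                          c(1, 1)), "non-finite")
  expect_error(imu_stream(numeric(0), numeric(0), numeric(0), numeric(0),
                          numeric(0), numeric(0)), "empty")
})

test_that("write/read round-trips fuzzed trials", {
  for (seed in 1:5) {
    counts <- 4 + sample(0:20, 7, replace = TRUE)
    tr <- make_tiny_trial(counts, noise_sd = 0.05, seed = seed)
    sp <- tempfile(fileext = ".csv")
    lp <- tempfile(fileext = ".csv")
    write_trial(tr, sp, lp)
    tr2 <- read_trial(sp, lp, fs = 128, subject_id = 1, fall_type = 1,
                      direction = "forward", repetition = 1)
    expect_equal(tr2$truth$labels, tr$truth$labels)
    for (ch in c("ax", "ay", "az", "gx", "gy", "gz")) {
      expect_equal(tr2$stream[[ch]], tr$stream[[ch]], tolerance = 1e-12)
    }
    # writing the reread trial reproduces the file content
    sp2 <- tempfile(fileext = ".csv")
    lp2 <- tempfile(fileext = ".csv")
    write_trial(tr2, sp2, lp2)
    expect_identical(readLines(lp2), readLines(lp))
    expect_identical(readLines(sp2), readLines(sp))
  }
})

test_that("per-sample label dialect reads equivalently", {
  tr <- make_tiny_trial()
  lp <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample = seq_along(tr$truth$labels) - 1L,
                       code = tr$truth$labels), lp, row.names = FALSE)
  expect_equal(read_labels_csv(lp)$labels, tr$truth$labels)
  # incomplete coverage
  write.csv(data.frame(sample = c(0, 2), code = c(0, 1)), lp,
            row.names = FALSE)
  expect_error(read_labels_csv(lp), "exactly once")
})

test_that("label sequence <-> timeline conversion is a bijection", {
  for (seed in 1:20) {
    set.seed(seed)
    labs <- random_label_sequence(sample(10:200, 1))
    seq <- phase_label_sequence(labs, fs = 128)
    tl <- labels_to_timeline(seq)
    expect_equal(timeline_to_labels(tl)$labels, labs)
    # intervals partition the samples, adjacent phases distinct
    expect_equal(tl$start_sample[1], 0L)
    expect_equal(tl$end_sample[nrow(tl)], length(labs) - 1L)
    if (nrow(tl) > 1) {
      expect_true(all(tl$start_sample[-1] == tl$end_sample[-nrow(tl)] + 1L))
      expect_true(all(diff(tl$phase) != 0))
    }
    expect_equal(tl$duration_s, (tl$end_sample - tl$start_sample + 1) / 128)
  }
})

test_that("timelines reject inconsistent intervals", {
  expect_error(phase_timeline(c(0, 1), c(0, 5), c(5, 10)), "overlap")
  expect_error(phase_timeline(c(0, 1), c(0, 3), c(4, 10)), "overlap")
  expect_error(phase_timeline(c(0, 1), c(0, 7), c(4, 10)), "gap")
  expect_error(phase_timeline(c(0, 0), c(0, 5), c(4, 10)), "share a phase")
  expect_error(phase_timeline(0, 3, 10), "start at sample 0")
})
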