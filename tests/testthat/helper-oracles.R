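# Shared fixtures and independent reference implementations used across
# the test files. The oracles deliberately use naive, literal arithmetic
# (per-window loops, all-pairs distances) so they stay independent of the
# optimized paths they check.

# A small well-formed trial with the given per-phase sample counts,
# deterministic content unless noise is requested.
make_tiny_trial <- function(counts = c(10, 10, 6, 6, 10, 10, 10), fs = 128,
                            noise_sd = 0, seed = 1) {
  stopifnot(length(counts) == 7)
  n <- sum(counts)
  set.seed(seed)
  base <- rep(c(1, 1.1, 0.5, 3, 0.2, 0.8, 1), counts)
  mk <- function(scale) scale * base + rnorm(n, 0, noise_sd)
  stream <- imu_stream(mk(0.1), mk(0.2), mk(1), mk(5), mk(10), mk(2), fs = fs)
  truth <- phase_label_sequence(rep(0:6, counts), fs = fs)
  trial_record(stream, truth, subject_id = 1L, fall_type = 1L,
               direction = "forward", repetition = 1L)
}

# Naive per-statistic feature oracle for one window of one channel.
stat_oracle <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  mx <- max(x)
  mn <- min(x)
  if (mx == mn) {
    c(mean = mu, std = 0, var = 0, max = mx, min = mn, range = 0,
      kurtosis = 0, skewness = 0)
  } else {
    m3 <- sum((x - mu)^3) / n
    m4 <- sum((x - mu)^4) / n
    c(mean = mu, std = sqrt(m2), var = m2, max = mx, min = mn,
      range = mx - mn, kurtosis = m4 / m2^2, skewness = m3 / m2^1.5)
  }
}

# Full 64-feature oracle for the window of W samples starting at `start`
# (0-based) of a stream.
feature_oracle <- function(stream, W, start) {
  idx <- (start + 1):(start + W)
  chans <- list(ax = stream$ax[idx], ay = stream$ay[idx], az = stream$az[idx],
                gx = stream$gx[idx], gy = stream$gy[idx], gz = stream$gz[idx])
  chans$a_r <- sqrt(chans$ax^2 + chans$ay^2 + chans$az^2)
  chans$g_r <- sqrt(chans$gx^2 + chans$gy^2 + chans$gz^2)
  out <- unlist(lapply(chans, stat_oracle))
  names(out) <- feature_names()
  out
}

# Brute-force all-pairs kNN vote with the package's documented tie rules:
# neighbours by (distance, training index); vote ties by smaller summed
# neighbour distance, then lower class code.
knn_oracle <- function(train, y, test, k) {
  apply(test, 1, function(q) {
    dist <- sqrt(colSums((t(train) - q)^2))
    ord <- order(dist)[1:k]
    lab <- y[ord]
    tb <- table(factor(lab, levels = 0:6))
    top <- as.integer(names(tb)[tb == max(tb)])
    if (length(top) > 1) {
      ds <- vapply(top, function(cl) sum(dist[ord][lab == cl]), numeric(1))
      top <- top[ds == min(ds)]
    }
    top[1]
  })
}

# A random contiguous 7-class label sequence (not necessarily all phases).
random_label_sequence <- function(n, n_runs = sample(1:6, 1)) {
  breaks <- sort(sample(seq_len(n - 1), min(n_runs, n - 1)))
  lens <- diff(c(0, breaks, n))
  labs <- sample(0:6, length(lens), replace = TRUE)
  # merge equal neighbours so runs are maximal
  rep(labs, lens)
}

# Separable 3-class Gaussian feature cloud in 64 dimensions.
make_cloud <- function(n_per_class = 60, sep = 8, seed = 1) {
  set.seed(seed)
  centers <- matrix(0, 3, 64)
  centers[2, 1:8] <- sep
  centers[3, 9:16] <- sep
  x <- do.call(rbind, lapply(1:3, function(cl) {
    matrix(rnorm(n_per_class * 64), n_per_class, 64) +
      matrix(centers[cl, ], n_per_class, 64, byrow = TRUE)
  }))
  list(x = x, y = rep(0:2, each = n_per_class))
}
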