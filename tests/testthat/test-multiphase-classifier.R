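test_that("classifier specs carry the studied hyperparameters", {
  s <- classifier_spec("knn")
  expect_equal(s$k, 13L)
  s <- classifier_spec("adaboost")
  expect_equal(s$adaboost_rounds, 10L)
  expect_equal(s$adaboost_weak_depth, 1L)
  s <- classifier_spec("svm")
  expect_equal(s$svm_kernel, "linear")
  expect_equal(s$svm_decomposition, "one-versus-one")
  expect_error(classifier_spec("knn", k = 12), "odd")
  expect_error(classifier_spec("boosting"), "arg")
})

test_that("training input is validated", {
  cloud <- make_cloud(20)
  expect_error(fit_multiphase(cloud$x, rep(0L, nrow(cloud$x))),
               "degenerate-training")
  bad <- cloud$x
  bad[3, 5] <- NaN
  expect_error(fit_multiphase(bad, cloud$y), "non-finite")
  m <- fit_multiphase(cloud$x, cloud$y, classifier_spec("knn", k = 1))
  expect_error(predict(m, cloud$x[, 1:10]), "64 feature")
  two_class <- c(1:3, 21:23)  # three points each of two classes
  expect_error(fit_multiphase(cloud$x[two_class, ], cloud$y[two_class],
                              classifier_spec("knn", k = 13)),
               "k exceeds")
})

test_that("kNN with k = 1 recalls its own training points", {
  cloud <- make_cloud(30, seed = 2)
  m <- fit_multiphase(cloud$x, cloud$y, classifier_spec("knn", k = 1))
  expect_equal(predict(m, cloud$x), cloud$y)
})

test_that("kNN prediction equals the brute-force voting oracle", {
  set.seed(31)
  ntr <- 900
  x <- matrix(rnorm(ntr * 64), ntr, 64)
  y <- sample(0:6, ntr, replace = TRUE)
  te <- matrix(rnorm(120 * 64), 120, 64)
  m <- fit_multiphase(x, y, classifier_spec("knn", k = 13))
  expect_equal(predict(m, te), unname(knn_oracle(x, y, te, 13)))
  # also under standardization (oracle fed the standardized coordinates)
  ms <- fit_multiphase(x, y, classifier_spec("knn", k = 13,
                                             standardize = TRUE))
  xs <- scale(x)
  tes <- scale(te, center = attr(xs, "scaled:center"),
               scale = attr(xs, "scaled:scale"))
  expect_equal(predict(ms, te),
               unname(knn_oracle(xs, y, tes, 13)))
})

test_that("naive Bayes recovers well-separated Gaussian clusters", {
  set.seed(8)
  n <- 80
  x <- rbind(matrix(rnorm(n * 64, 0), n, 64),
             matrix(rnorm(n * 64, 5), n, 64))
  y <- rep(c(0L, 3L), each = n)
  te <- rbind(matrix(rnorm(40 * 64, 0), 40, 64),
              matrix(rnorm(40 * 64, 5), 40, 64))
  yte <- rep(c(0L, 3L), each = 40)
  m <- fit_multiphase(x, y, classifier_spec("nb"))
  expect_equal(predict(m, te), yte)
  # cross-check the Gaussian MAP rule against an independent implementation
  ref <- e1071::naiveBayes(x, factor(y))
  ref_pred <- as.integer(as.character(predict(ref, te)))
  expect_equal(predict(m, te), ref_pred)
})

test_that("all five techniques separate an easy 3-class cloud", {
  cloud <- make_cloud(60, sep = 8, seed = 5)
  test <- make_cloud(40, sep = 8, seed = 6)
  for (tech in c("knn", "svm", "nb", "dt", "adaboost")) {
    m <- fit_multiphase(cloud$x, cloud$y, classifier_spec(tech))
    acc <- mean(predict(m, test$x) == test$y)
    expect_gte(acc, 0.95)
  }
})

test_that("fits are deterministic given identical data and spec", {
  cloud <- make_cloud(40, sep = 3, seed = 9)
  probe <- make_cloud(30, sep = 3, seed = 10)$x
  for (tech in c("knn", "svm", "nb", "dt", "adaboost")) {
    m1 <- fit_multiphase(cloud$x, cloud$y, classifier_spec(tech))
    m2 <- fit_multiphase(cloud$x, cloud$y, classifier_spec(tech))
    expect_identical(predict(m1, probe), predict(m2, probe))
  }
})

test_that("standardization leaves decision-tree predictions unchanged", {
  cloud <- make_cloud(50, sep = 2, seed = 12)
  probe <- make_cloud(40, sep = 2, seed = 13)$x
  m_raw <- fit_multiphase(cloud$x, cloud$y,
                          classifier_spec("dt", standardize = FALSE))
  m_std <- fit_multiphase(cloud$x, cloud$y,
                          classifier_spec("dt", standardize = TRUE))
  expect_identical(predict(m_raw, probe), predict(m_std, probe))
})

test_that("predictions stay inside the 7-phase vocabulary", {
  cloud <- make_cloud(30, sep = 1, seed = 14)  # overlapping, hard
  probe <- matrix(rnorm(200 * 64, 2, 4), 200, 64)
  for (tech in c("knn", "svm", "nb", "dt", "adaboost")) {
    m <- fit_multiphase(cloud$x, cloud$y, classifier_spec(tech))
    p <- predict(m, probe)
    expect_true(all(p %in% 0:6))
  }
})

test_that("models round-trip through the save format", {
  cloud <- make_cloud(30, seed = 15)
  probe <- make_cloud(20, seed = 16)$x
  m <- fit_multiphase(cloud$x, cloud$y, classifier_spec("knn"))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m, probe), predict(m2, probe))
  saveRDS(list(format = "other"), path)
  expect_error(load_model(path), "not a fallphase model")
})
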