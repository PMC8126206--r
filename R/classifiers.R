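#' Classifier specification
#'
#' A uniform description of the five phase-classification techniques and
#' their hyperparameters. Defaults follow the configuration studied for
#' this pipeline: a linear one-versus-one SVM; kNN with Euclidean distance
#' and k = 13; Gaussian naive Bayes with the MAP decision rule; CART with
#' the Gini splitting rule, grown unpruned; and multiclass AdaBoost (SAMME)
#' over depth-1 decision trees with 10 boosting rounds.
#'
#' @param technique One of `"knn"`, `"svm"`, `"nb"`, `"dt"`, `"adaboost"`.
#' @param k Neighbour count for kNN (odd, >= 1).
#' @param svm_cost SVM regularization constant C.
#' @param adaboost_rounds Number of boosting rounds (>= 1).
#' @param adaboost_weak_depth Depth of the boosted weak trees.
#' @param nb_var_floor Per-feature variance floor for naive Bayes, so
#'   near-constant features keep a proper Gaussian likelihood.
#' @param standardize Fit per-feature z-score standardization on the
#'   training data and apply it at prediction time. Off by default: the
#'   features are left in their native units (g, deg/s), matching the
#'   default behaviour of the reference computing environment the pipeline
#'   was configured after; global z-scoring compresses the low-amplitude
#'   contrasts (quiet-standing posture offsets) that the distance-based
#'   classifiers rely on. The flag makes both behaviours reproducible.
#' @param seed Integer seed recorded in the spec; the five fits are
#'   themselves deterministic.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(technique = c("knn", "svm", "nb", "dt", "adaboost"),
                            k = 13L, svm_cost = 1, adaboost_rounds = 10L,
                            adaboost_weak_depth = 1L, nb_var_floor = 1e-9,
                            standardize = FALSE, seed = 1L) {
  technique <- match.arg(technique)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k %% 2L == 0L) {
    stop("k must be an odd integer >= 1", call. = FALSE)
  }
  if (adaboost_rounds < 1L) stop("adaboost_rounds must be >= 1", call. = FALSE)
  if (nb_var_floor <= 0) stop("nb_var_floor must be positive", call. = FALSE)
  structure(list(technique = technique, k = k, svm_cost = svm_cost,
                 svm_kernel = "linear", svm_decomposition = "one-versus-one",
                 nb_family = "gaussian", dt_split = "gini",
                 adaboost_rounds = as.integer(adaboost_rounds),
                 adaboost_weak_depth = as.integer(adaboost_weak_depth),
                 nb_var_floor = nb_var_floor,
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

check_feature_matrix <- function(x, n_features = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) {
    stop("validation error: non-finite feature values", call. = FALSE)
  }
  if (!is.null(n_features) && ncol(x) != n_features) {
    stop("validation error: expected ", n_features, " feature columns, got ",
         ncol(x), call. = FALSE)
  }
  x
}

fit_standardizer <- function(x, enabled) {
  if (!enabled) {
    return(list(center = rep(0, ncol(x)), scale = rep(1, ncol(x))))
  }
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(x, std) {
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

#' Fit a multiphase classifier
#'
#' Trains the technique named in `spec` on segment feature vectors and
#' their phase labels. Standardization statistics, when enabled, are
#' computed from these training data only and stored in the model so test
#' folds are transformed with the training fold's statistics.
#'
#' @param x Numeric feature matrix (rows = segments, columns = features;
#'   64 in the standard pipeline).
#' @param y Integer phase codes in 0--6, one per row of `x`.
#' @param spec A [classifier_spec()].
#' @return An object of class `multiphase_model`.
#' @export
fit_multiphase <- function(x, y, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- check_feature_matrix(x)
  y <- check_phase_codes(y)
  if (length(y) != nrow(x)) {
    stop("validation error: nrow(x) != length(y)", call. = FALSE)
  }
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    stop("degenerate-training: need examples of at least 2 classes",
         call. = FALSE)
  }
  if (spec$technique == "knn" && spec$k > nrow(x)) {
    stop("validation error: k exceeds the number of training segments",
         call. = FALSE)
  }
  std <- fit_standardizer(x, spec$standardize)
  xs <- apply_standardizer(x, std)

  fit <- switch(spec$technique,
    knn = {
      build <- knn_build_cpp(xs)
      list(build = build, y = as.integer(y[build$orig_idx + 1L]))
    },
    svm = e1071::svm(xs, factor(y, levels = classes), kernel = "linear",
                     cost = spec$svm_cost, scale = FALSE),
    nb = fit_gnb(xs, y, classes, spec$nb_var_floor),
    dt = fit_cart(xs, y, classes, maxdepth = 30L),
    adaboost = fit_samme(xs, y, classes, spec))

  structure(list(technique = spec$technique, spec = spec, std = std,
                 classes = classes, n_features = ncol(x), fit = fit),
            class = "multiphase_model")
}

#' @export
print.multiphase_model <- function(x, ...) {
  cat(sprintf("<multiphase_model> technique=%s, %d features, classes {%s}\n",
              x$technique, x$n_features, paste(x$classes, collapse = ",")))
  invisible(x)
}

#' Predict phase labels for segments
#'
#' @param object A `multiphase_model` from [fit_multiphase()].
#' @param x Feature matrix with the model's fitted dimensionality.
#' @param ... Unused.
#' @return Integer vector of phase codes in 0--6, one per row of `x`.
#' @export
predict.multiphase_model <- function(object, x, ...) {
  x <- check_feature_matrix(x, object$n_features)
  xs <- apply_standardizer(x, object$std)
  switch(object$technique,
    knn = as.integer(knn_query_cpp(object$fit$build, object$fit$y, xs,
                                   object$spec$k, 7L)),
    svm = predict_svm_ovo(object$fit, xs),
    nb = predict_gnb(object$fit, xs),
    dt = predict_cart(object$fit, xs),
    adaboost = predict_samme(object$fit, xs))
}

# --- Gaussian naive Bayes (MAP rule, log space, variance floor) ----------

fit_gnb <- function(x, y, classes, var_floor) {
  mu <- t(vapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                 numeric(ncol(x))))
  va <- t(vapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    pmax(colMeans(xi^2) - colMeans(xi)^2, var_floor)
  }, numeric(ncol(x))))
  prior <- as.numeric(table(factor(y, levels = classes))) / length(y)
  list(classes = classes, mu = mu, var = va, log_prior = log(prior))
}

predict_gnb <- function(fit, x) {
  n <- nrow(x)
  ll <- matrix(0, n, length(fit$classes))
  for (ci in seq_along(fit$classes)) {
    mu <- fit$mu[ci, ]
    va <- fit$var[ci, ]
    d <- sweep(x, 2, mu, "-")
    ll[, ci] <- fit$log_prior[ci] -
      0.5 * sum(log(2 * pi * va)) -
      0.5 * rowSums(sweep(d^2, 2, va, "/"))
  }
  fit$classes[max.col(ll, ties.method = "first")]
}

# --- CART (Gini splits, unpruned) ----------------------------------------

fit_cart <- function(x, y, classes, maxdepth, weights = NULL) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- factor(y, levels = classes)
  rpart::rpart(.y ~ ., data = df, method = "class",
               weights = weights,
               parms = list(split = "gini"),
               control = rpart::rpart.control(minsplit = 2L, minbucket = 1L,
                                              cp = 0, xval = 0L,
                                              maxdepth = maxdepth))
}

predict_cart <- function(fit, x) {
  df <- as.data.frame(x)
  names(df) <- attr(fit$terms, "term.labels")
  as.integer(as.character(predict(fit, df, type = "class")))
}

# --- multiclass AdaBoost (SAMME over decision stumps) --------------------

fit_samme <- function(x, y, classes, spec) {
  n <- nrow(x)
  K <- length(classes)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  for (t in seq_len(spec$adaboost_rounds)) {
    tree <- fit_cart(x, y, classes, maxdepth = spec$adaboost_weak_depth,
                     weights = w * n)
    pred <- predict_cart(tree, x)
    miss <- pred != y
    err <- sum(w[miss])
    if (err >= 1 - 1 / K) break          # weak learner no better than chance
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    learners[[length(learners) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    if (sum(miss) == 0L) break           # perfect learner dominates the vote
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  if (length(learners) == 0L) {          # fall back to a single stump
    learners <- list(fit_cart(x, y, classes,
                              maxdepth = spec$adaboost_weak_depth))
    alphas <- 1
  }
  list(classes = classes, learners = learners, alphas = alphas)
}

predict_samme <- function(fit, x) {
  votes <- matrix(0, nrow(x), length(fit$classes))
  for (t in seq_along(fit$learners)) {
    pred <- predict_cart(fit$learners[[t]], x)
    idx <- match(pred, fit$classes)
    votes[cbind(seq_len(nrow(x)), idx)] <-
      votes[cbind(seq_len(nrow(x)), idx)] + fit$alphas[t]
  }
  fit$classes[max.col(votes, ties.method = "first")]
}

# --- one-versus-one SVM vote with margin tie-break -----------------------

predict_svm_ovo <- function(fit, x) {
  pr <- predict(fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  classes <- as.integer(as.character(fit$levels))
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  n <- nrow(x)
  votes <- matrix(0L, n, length(classes))
  margin <- matrix(0, n, length(classes))
  for (p in seq_along(pairs)) {
    a <- match(as.integer(pairs[[p]][1]), classes)
    b <- match(as.integer(pairs[[p]][2]), classes)
    pos <- dv[, p] >= 0
    votes[, a] <- votes[, a] + pos
    votes[, b] <- votes[, b] + !pos
    margin[, a] <- margin[, a] + dv[, p]
    margin[, b] <- margin[, b] - dv[, p]
  }
  out <- integer(n)
  for (i in seq_len(n)) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1L) {
      top <- top[order(-margin[i, top], classes[top])][1L]
    }
    out[i] <- classes[top]
  }
  out
}

#' Save / load a fitted multiphase model
#'
#' Serializes the fitted state together with its [classifier_spec()] and
#' standardization statistics, with a format version tag.
#'
#' @param model A `multiphase_model`.
#' @param path File path.
#' @return `load_model()`: the restored `multiphase_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "multiphase_model"))
  saveRDS(list(format = "fallphase-model-1", model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "fallphase-model-1")) {
    stop("validation error: not a fallphase model archive", call. = FALSE)
  }
  obj$model
}
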