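# Fit/predict engines behind the registry. Every engine receives a samples x
# features numeric matrix X (already restricted to the active gene subset)
# and an integer 0/1 label vector, and returns 0/1 predictions. Scale- and
# distance-sensitive learners see features standardized with training
# means/sds; zero-variance features are dropped at fit time.

.standardized_keys <- c(
  "linear_svm", "quadratic_svm", "cubic_svm",
  "fine_gaussian_svm", "medium_gaussian_svm", "coarse_gaussian_svm",
  "fine_knn", "medium_knn", "coarse_knn",
  "cosine_knn", "cubic_knn", "weighted_knn",
  "subspace_knn", "ann")

#' Fit a registry model
#'
#' @param spec a [model_spec()].
#' @param X numeric matrix, samples x features.
#' @param y integer 0/1 labels.
#' @param seed integer seed applied to stochastic learners; defaults to the
#'   spec's own seed or 0.
#' @return an `ibdsig_model` usable with [predict_model()].
#' @export
fit_model <- function(spec, X, y, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (ncol(X) < 1L) {
    stop_ibdsig("cannot fit a model on an empty feature set",
                "ibdsig_dim_error")
  }
  sds <- apply(X, 2L, stats::sd)
  keep <- which(sds > 0)
  if (!length(keep)) keep <- 1L  # all-constant: engines degrade to priors
  Xk <- X[, keep, drop = FALSE]
  center <- scl <- NULL
  if (spec$key %in% .standardized_keys) {
    center <- colMeans(Xk)
    scl <- pmax(apply(Xk, 2L, stats::sd), 1e-12)
    Xk <- sweep(sweep(Xk, 2L, center), 2L, scl, "/")
  }
  seed <- as.integer(seed %||% spec$seed %||% 0L)
  fit <- withr::with_seed(seed, .fit_engine(spec$key)(Xk, y, spec$hyper))
  structure(list(spec = spec, keep = keep, center = center, scale = scl,
                 fit = fit, n_features = ncol(X)),
            class = "ibdsig_model")
}

#' Predict 0/1 classes from a fitted registry model
#'
#' @param model an `ibdsig_model` from [fit_model()].
#' @param X numeric matrix, samples x features, with the same feature
#'   columns the model was fitted on.
#' @return integer vector of 0/1 predictions.
#' @export
predict_model <- function(model, X) {
  stopifnot(inherits(model, "ibdsig_model"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != model$n_features) {
    stop_ibdsig("prediction matrix has a different number of features than training",
                "ibdsig_dim_error")
  }
  Xk <- X[, model$keep, drop = FALSE]
  if (!is.null(model$center)) {
    Xk <- sweep(sweep(Xk, 2L, model$center), 2L, model$scale, "/")
  }
  as.integer(.predict_engine(model$spec$key)(model$fit, Xk))
}

# ---- engine dispatch --------------------------------------------------------

.fit_engine <- function(key) {
  switch(key,
    complex_tree = , medium_tree = , simple_tree = .fit_tree,
    linear_discriminant = .fit_lda,
    quadratic_discriminant = .fit_qda,
    logistic_regression = .fit_logistic,
    linear_svm = function(X, y, h) .fit_svm(X, y, h, kernel = "linear"),
    quadratic_svm = , cubic_svm =
      function(X, y, h) .fit_svm(X, y, h, kernel = "polynomial"),
    fine_gaussian_svm = , medium_gaussian_svm = , coarse_gaussian_svm =
      function(X, y, h) .fit_svm(X, y, h, kernel = "radial"),
    fine_knn = , medium_knn = , coarse_knn =
      function(X, y, h) .fit_knn(X, y, h, metric = "euclidean"),
    cosine_knn = function(X, y, h) .fit_knn(X, y, h, metric = "cosine"),
    cubic_knn = function(X, y, h) .fit_knn(X, y, h, metric = "minkowski3"),
    weighted_knn = function(X, y, h)
      .fit_knn(X, y, h, metric = "euclidean", weighted = TRUE),
    boosted_trees = .fit_boosted,
    bagged_trees = .fit_bagged,
    subspace_discriminant = function(X, y, h)
      .fit_subspace(X, y, h, learner = "lda"),
    subspace_knn = function(X, y, h) .fit_subspace(X, y, h, learner = "knn"),
    rusboosted_trees = .fit_rusboost,
    majority_vote = .fit_majority,
    ann = .fit_ann,
    stop_ibdsig(sprintf("no engine for key '%s'", key),
                "ibdsig_registry_error"))
}

.predict_engine <- function(key) {
  switch(key,
    complex_tree = , medium_tree = , simple_tree = .predict_tree,
    linear_discriminant = , quadratic_discriminant = .predict_da,
    logistic_regression = .predict_logistic,
    linear_svm = , quadratic_svm = , cubic_svm = ,
    fine_gaussian_svm = , medium_gaussian_svm = , coarse_gaussian_svm =
      .predict_svm,
    fine_knn = , medium_knn = , coarse_knn = , cosine_knn = , cubic_knn = ,
    weighted_knn = .predict_knn,
    boosted_trees = .predict_boosted,
    bagged_trees = .predict_bagged,
    subspace_discriminant = , subspace_knn = .predict_subspace,
    rusboosted_trees = .predict_rusboost,
    majority_vote = .predict_majority,
    ann = .predict_ann,
    stop_ibdsig(sprintf("no engine for key '%s'", key),
                "ibdsig_registry_error"))
}

.majority_class <- function(y) {
  if (sum(y == 1L) > sum(y == 0L)) 1L else 0L
}

# ---- decision trees ---------------------------------------------------------

.tree_frame <- function(X) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df
}

.fit_tree <- function(X, y, h) {
  df <- .tree_frame(X)
  df$.y <- factor(y, levels = c(0L, 1L))
  rpart::rpart(.y ~ ., data = df, method = "class",
               control = rpart::rpart.control(
                 maxdepth = h$maxdepth, cp = h$cp, minsplit = 4L,
                 xval = 0L))
}

.predict_tree <- function(fit, X) {
  as.integer(as.character(
    stats::predict(fit, newdata = .tree_frame(X), type = "class")))
}

# ---- discriminant analysis --------------------------------------------------

# Diagonal-covariance Gaussian classifier: the well-conditioned fallback
# when lda/qda are singular (p close to or above the class sizes).
.fit_diag_gaussian <- function(X, y) {
  cls <- sort(unique(y))
  stats <- lapply(cls, function(c) {
    Xi <- X[y == c, , drop = FALSE]
    list(mu = colMeans(Xi),
         sd = pmax(apply(Xi, 2L, stats::sd), 1e-6),
         logprior = log(nrow(Xi) / nrow(X)))
  })
  list(type = "diag", classes = cls, stats = stats)
}

.predict_diag_gaussian <- function(fit, X) {
  ll <- vapply(fit$stats, function(s) {
    rowSums(stats::dnorm(sweep(X, 2L, s$mu), sd = rep(s$sd, each = nrow(X)),
                         log = TRUE)) + s$logprior
  }, numeric(nrow(X)))
  ll <- matrix(ll, nrow = nrow(X))
  fit$classes[max.col(ll, ties.method = "first")]
}

.fit_lda <- function(X, y, h) {
  tryCatch(
    list(type = "mass",
         fit = suppressWarnings(MASS::lda(X, grouping = factor(y)))),
    error = function(e) .fit_diag_gaussian(X, y))
}

.fit_qda <- function(X, y, h) {
  ok <- min(table(y)) > ncol(X)
  if (!ok) return(.fit_diag_gaussian(X, y))
  tryCatch(
    list(type = "mass",
         fit = suppressWarnings(MASS::qda(X, grouping = factor(y)))),
    error = function(e) .fit_diag_gaussian(X, y))
}

.predict_da <- function(fit, X) {
  if (identical(fit$type, "diag")) return(.predict_diag_gaussian(fit, X))
  as.integer(as.character(stats::predict(fit$fit, X)$class))
}

# ---- logistic regression ----------------------------------------------------

.fit_logistic <- function(X, y, h) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
  beta <- fit$coefficients
  beta[!is.finite(beta)] <- 0
  list(beta = beta)
}

.predict_logistic <- function(fit, X) {
  as.integer(drop(cbind(1, X) %*% fit$beta) > 0)
}

# ---- support vector machines ------------------------------------------------

.fit_svm <- function(X, y, h, kernel) {
  args <- list(x = X, y = factor(y, levels = c(0L, 1L)), kernel = kernel,
               cost = h$cost, scale = FALSE)
  if (kernel == "polynomial") {
    args$degree <- h$degree
    args$coef0 <- h$coef0
    args$gamma <- 1 / ncol(X)
  }
  if (kernel == "radial") {
    # kernel scale ks = scale_factor * sqrt(p)  =>  gamma = 1 / ks^2
    ks <- h$scale_factor * sqrt(ncol(X))
    args$gamma <- 1 / ks^2
  }
  do.call(e1071::svm, args)
}

.predict_svm <- function(fit, X) {
  as.integer(as.character(stats::predict(fit, X)))
}

# ---- k-nearest neighbours ---------------------------------------------------

# One deterministic KNN engine for every metric/weight variant: distances
# are computed explicitly; neighbour ties are broken by training index and
# vote ties by the larger training class (then class 0), so repeated calls
# agree exactly.
.knn_dist <- function(Xtr, Xte, metric) {
  switch(metric,
    euclidean = {
      d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") -
        2 * tcrossprod(Xte, Xtr)
      sqrt(pmax(d2, 0))
    },
    cosine = {
      ntr <- sqrt(pmax(rowSums(Xtr^2), 1e-24))
      nte <- sqrt(pmax(rowSums(Xte^2), 1e-24))
      1 - tcrossprod(Xte / nte, Xtr / ntr)
    },
    minkowski3 = {
      t(apply(Xte, 1L, function(z)
        colSums(abs(t(Xtr) - z)^3)^(1 / 3)))
    })
}

.fit_knn <- function(X, y, h, metric, weighted = FALSE) {
  list(X = X, y = y, k = min(h$k, nrow(X)), metric = metric,
       weighted = weighted, majority = .majority_class(y))
}

.predict_knn <- function(fit, X) {
  D <- .knn_dist(fit$X, X, fit$metric)
  D <- matrix(D, nrow = nrow(X))
  if (fit$k == 1L && !fit$weighted) {
    return(fit$y[max.col(-D, ties.method = "first")])
  }
  apply(D, 1L, function(d) {
    nb <- order(d, seq_along(d))[seq_len(fit$k)]
    w <- if (fit$weighted) 1 / pmax(d[nb], 1e-12)^2 else rep(1, fit$k)
    s1 <- sum(w[fit$y[nb] == 1L])
    s0 <- sum(w) - s1
    if (s1 > s0) 1L else if (s0 > s1) 0L else fit$majority
  })
}

# ---- ensembles --------------------------------------------------------------

.fit_boosted <- function(X, y, h) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = h$learn_rate,
                  max_depth = h$maxdepth, nthread = 1L),
    data = dtrain, nrounds = h$n_learners, verbose = 0L)
}

.predict_boosted <- function(fit, X) {
  as.integer(stats::predict(fit, xgboost::xgb.DMatrix(X, nthread = 1L)) > 0.5)
}

.fit_bagged <- function(X, y, h) {
  # bootstrap aggregation of unpruned trees: a random forest with every
  # feature eligible at every split
  randomForest::randomForest(x = X, y = factor(y, levels = c(0L, 1L)),
                             ntree = h$n_learners, mtry = ncol(X))
}

.predict_bagged <- function(fit, X) {
  as.integer(as.character(stats::predict(fit, X)))
}

.fit_subspace <- function(X, y, h, learner) {
  p <- ncol(X)
  d <- max(1L, floor(p / 2))
  members <- lapply(seq_len(h$n_learners), function(i) {
    idx <- sort(sample.int(p, d))
    sub <- X[, idx, drop = FALSE]
    fit <- if (learner == "lda") .fit_lda(sub, y, list())
           else .fit_knn(sub, y, list(k = h$k), metric = "euclidean")
    list(idx = idx, fit = fit)
  })
  list(members = members, learner = learner, majority = .majority_class(y))
}

.predict_subspace <- function(fit, X) {
  votes <- vapply(fit$members, function(mb) {
    sub <- X[, mb$idx, drop = FALSE]
    if (fit$learner == "lda") as.numeric(.predict_da(mb$fit, sub))
    else as.numeric(.predict_knn(mb$fit, sub))
  }, numeric(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  share <- rowMeans(votes)
  ifelse(share > 0.5, 1L, ifelse(share < 0.5, 0L, fit$majority))
}

# RUSBoost: AdaBoost.M1 over shallow trees where each round is trained on a
# class-balanced random undersample drawn with the current boosting weights.
.fit_rusboost <- function(X, y, h) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  members <- list()
  cls_idx <- split(seq_len(n), y)
  n_min <- min(lengths(cls_idx))
  for (r in seq_len(h$n_learners)) {
    take <- unlist(lapply(cls_idx, function(idx) {
      if (length(idx) <= n_min) idx
      else sample(idx, n_min, prob = w[idx] / sum(w[idx]))
    }), use.names = FALSE)
    tree <- .fit_tree(X[take, , drop = FALSE], y[take],
                      list(maxdepth = h$maxdepth, cp = 0))
    pred <- .predict_tree(tree, X)
    err <- sum(w * (pred != y))
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- h$learn_rate * 0.5 * log((1 - err) / err)
    members[[length(members) + 1L]] <- list(tree = tree, alpha = alpha)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    if (err < 1e-9) break
  }
  list(members = members, majority = .majority_class(y))
}

.predict_rusboost <- function(fit, X) {
  if (!length(fit$members)) return(rep(fit$majority, nrow(X)))
  score <- rowSums(matrix(vapply(fit$members, function(mb) {
    mb$alpha * (2 * .predict_tree(mb$tree, X) - 1)
  }, numeric(nrow(X))), nrow = nrow(X)))
  ifelse(score > 0, 1L, ifelse(score < 0, 0L, fit$majority))
}

# ---- baselines --------------------------------------------------------------

.fit_majority <- function(X, y, h) list(class = .majority_class(y))

.predict_majority <- function(fit, X) rep(fit$class, nrow(X))

.fit_ann <- function(X, y, h) {
  mlp_fit(X, y, layers = h$layers, width = h$width, epochs = h$epochs,
          learn_rate = h$learn_rate)
}

.predict_ann <- function(fit, X) mlp_predict(fit, X)
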