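#' Confusion counts and derived metrics
#'
#' The positive class is label 1 throughout (IBD in the control-vs-IBD task,
#' CD in the UC-vs-CD task). Ratios with a zero denominator (e.g.
#' specificity when the evaluation set has no negatives) are reported as
#' `NA` rather than coerced to 0, so degenerate evaluation sets are visible
#' instead of silently corrupting leaderboards.
#'
#' @param truth,pred integer 0/1 vectors of equal length.
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred),
            all(truth %in% 0:1), all(pred %in% 0:1))
  c(tp = sum(truth == 1L & pred == 1L),
    fp = sum(truth == 0L & pred == 1L),
    tn = sum(truth == 0L & pred == 0L),
    fn = sum(truth == 1L & pred == 0L))
}

#' @param tp,fp,tn,fn non-negative confusion counts.
#' @rdname confusion_counts
#' @export
eval_metrics <- function(tp, fp, tn, fn) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = ratio(tp + tn, tp + fp + tn + fn),
       sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp))
}

.eval_result <- function(spec, subset, counts, tag, cv_accuracy = NA_real_,
                         fold_accuracies = NULL) {
  met <- eval_metrics(counts[["tp"]], counts[["fp"]], counts[["tn"]],
                      counts[["fn"]])
  structure(
    list(key = spec$key, spec = spec, subset = subset,
         counts = counts, accuracy = met$accuracy,
         sensitivity = met$sensitivity, specificity = met$specificity,
         cv_accuracy = cv_accuracy, fold_accuracies = fold_accuracies,
         tag = tag),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result:%s> %s | %d genes | acc %.3f sens %.3f spec %.3f\n",
              x$tag, x$key, length(x$subset),
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Seeded (stratified) fold assignment
#'
#' @param y integer 0/1 labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @param stratify assign folds within each class (default), keeping class
#'   balance near-equal across folds.
#' @return integer fold id in `1..k` per sample.
#' @export
make_folds <- function(y, k, seed = 1L, stratify = TRUE) {
  n <- length(y)
  if (k < 2L || k > n) {
    stop_ibdsig("k folds must satisfy 2 <= k <= n samples",
                "ibdsig_value_error")
  }
  withr::with_seed(as.integer(seed), {
    fold <- integer(n)
    if (stratify) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
    fold
  })
}

#' k-fold cross-validation of one model spec
#'
#' Fits the spec on each training fold-complement and predicts the held-out
#' fold. `cv_accuracy` is the mean of the per-fold accuracies; confusion
#' counts are pooled over folds. Folds are a seeded stratified partition by
#' default, so every fold sees both classes.
#'
#' @param spec a [model_spec()].
#' @param X numeric matrix, samples x features.
#' @param y integer 0/1 labels.
#' @param k_folds number of folds (default 10).
#' @param seed integer master seed; fold assignment and per-fold learner
#'   seeds are derived from it.
#' @param stratify stratify folds by label (default `TRUE`).
#' @param subset optional [gene_subset()] recorded on the result.
#' @return an `eval_result` with tag `"cv"`.
#' @export
cross_validate <- function(spec, X, y, k_folds = 10L, seed = 1L,
                           stratify = TRUE, subset = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop_ibdsig("training labels contain a single class",
                "ibdsig_single_class_error")
  }
  fold <- make_folds(y, k_folds, seed = derive_seed(seed, "folds"),
                     stratify = stratify)
  counts <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  fold_acc <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) {
      stop_ibdsig(
        "a fold complement contains a single class; use stratified folds",
        "ibdsig_single_class_error")
    }
    model <- fit_model(spec, X[tr, , drop = FALSE], y[tr],
                       seed = derive_seed(seed, spec$key, "fold", f))
    pred <- predict_model(model, X[!tr, , drop = FALSE])
    cf <- confusion_counts(y[!tr], pred)
    counts <- counts + cf
    fold_acc[f] <- (cf[["tp"]] + cf[["tn"]]) / sum(cf)
  }
  .eval_result(spec, subset, counts, tag = "cv",
               cv_accuracy = mean(fold_acc), fold_accuracies = fold_acc)
}

#' Fit on the training set and evaluate on the held-out test set
#'
#' @param spec a [model_spec()].
#' @param subset a [gene_subset()] restricting the feature columns; `NULL`
#'   uses all features.
#' @param X_train,X_test numeric matrices, samples x genes (full gene set).
#' @param y_train,y_test integer 0/1 labels.
#' @param seed integer seed for stochastic learners.
#' @return an `eval_result` with tag `"test"`.
#' @export
fit_and_evaluate <- function(spec, subset, X_train, y_train, X_test, y_test,
                             seed = 1L) {
  if (!is.null(subset)) {
    if (!length(subset$indices)) {
      stop_ibdsig("cannot evaluate an empty gene subset", "ibdsig_dim_error")
    }
    X_train <- X_train[, subset$indices, drop = FALSE]
    X_test <- X_test[, subset$indices, drop = FALSE]
  }
  model <- fit_model(spec, X_train, y_train,
                     seed = derive_seed(seed, spec$key, "final"))
  pred <- predict_model(model, X_test)
  .eval_result(spec, subset, confusion_counts(y_test, pred), tag = "test")
}

#' The multilayer perceptron baseline spec
#'
#' Builds a [model_spec()] for a network of `layers` hidden layers of
#' `width` neurons each, conforming to the registry fit/predict contract.
#'
#' @param layers number of hidden layers (>= 1).
#' @param width neurons per hidden layer; default 30.
#' @param ... further hyperparameter overrides (`epochs`, `learn_rate`).
#' @return a [model_spec()] with key `"ann"`.
#' @export
ann_classifier <- function(layers, width = 30L, ...) {
  if (!is.numeric(layers) || layers < 1L) {
    stop_ibdsig("layers must be >= 1", "ibdsig_value_error")
  }
  model_spec("ann", hyper = c(list(layers = as.integer(layers),
                                   width = as.integer(width)), list(...)))
}
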