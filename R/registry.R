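# The 23-algorithm registry: a fixed table of classifier presets behind one
# uniform fit/predict contract. Names follow the conventional point-and-click
# preset families (tree complexity tiers, discriminants, SVM kernels, KNN
# metric/weight variants, tree ensembles); the frozen default
# hyperparameters are documented on registry_defaults().

.registry_keys <- c(
  "complex_tree", "medium_tree", "simple_tree",
  "linear_discriminant", "quadratic_discriminant", "logistic_regression",
  "linear_svm", "quadratic_svm", "cubic_svm",
  "fine_gaussian_svm", "medium_gaussian_svm", "coarse_gaussian_svm",
  "fine_knn", "medium_knn", "coarse_knn",
  "cosine_knn", "cubic_knn", "weighted_knn",
  "boosted_trees", "bagged_trees",
  "subspace_discriminant", "subspace_knn", "rusboosted_trees")

# extra diagnostic / baseline keys usable via model_spec() but not part of
# the 23-entry registry
.extra_keys <- c("majority_vote", "ann")

#' Default hyperparameters of every registry entry
#'
#' The presets are frozen in one place so fidelity experiments can retune
#' without code changes: tree tiers cap depth at 10/5/2; KNN tiers use
#' k = 1/10/100 (capped at the training size); Gaussian SVM tiers use kernel
#' scale sqrt(p)/4, sqrt(p) and 4*sqrt(p) for p features; all ensembles use
#' 30 learners, boosting with learning rate 0.1, subspace ensembles with
#' feature subspaces of size floor(p/2).
#'
#' @return named list of default hyperparameter lists, one per key.
#' @export
registry_defaults <- function() {
  list(
    complex_tree = list(maxdepth = 10L, cp = 1e-4),
    medium_tree = list(maxdepth = 5L, cp = 1e-3),
    simple_tree = list(maxdepth = 2L, cp = 1e-2),
    linear_discriminant = list(),
    quadratic_discriminant = list(),
    logistic_regression = list(),
    linear_svm = list(cost = 1),
    quadratic_svm = list(cost = 1, degree = 2L, coef0 = 1),
    cubic_svm = list(cost = 1, degree = 3L, coef0 = 1),
    fine_gaussian_svm = list(cost = 1, scale_factor = 0.25),
    medium_gaussian_svm = list(cost = 1, scale_factor = 1),
    coarse_gaussian_svm = list(cost = 1, scale_factor = 4),
    fine_knn = list(k = 1L),
    medium_knn = list(k = 10L),
    coarse_knn = list(k = 100L),
    cosine_knn = list(k = 10L),
    cubic_knn = list(k = 10L),
    weighted_knn = list(k = 10L),
    boosted_trees = list(n_learners = 30L, learn_rate = 0.1, maxdepth = 3L),
    bagged_trees = list(n_learners = 30L),
    subspace_discriminant = list(n_learners = 30L),
    subspace_knn = list(n_learners = 30L, k = 1L),
    rusboosted_trees = list(n_learners = 30L, learn_rate = 0.1,
                            maxdepth = 2L),
    majority_vote = list(),
    ann = list(layers = 1L, width = 30L, epochs = 150L, learn_rate = 0.01))
}

#' Build a model specification
#'
#' @param key a registry key (see [registry_list()]), or one of the extra
#'   keys `"majority_vote"` (baseline diagnostic) and `"ann"` (multilayer
#'   perceptron, used by the layer sweep).
#' @param hyper named list of hyperparameter overrides, validated against
#'   the key's defaults.
#' @param seed integer seed for stochastic learners; `NULL` means the
#'   caller's fan-out seed is used.
#' @return a `model_spec`.
#' @export
model_spec <- function(key, hyper = list(), seed = NULL) {
  defaults <- registry_defaults()
  if (!key %in% c(.registry_keys, .extra_keys)) {
    stop_ibdsig(sprintf("unknown model key '%s'", key),
                "ibdsig_registry_error")
  }
  base <- defaults[[key]]
  unknown <- setdiff(names(hyper), names(base))
  if (length(unknown)) {
    stop_ibdsig(sprintf("unknown hyperparameter '%s' for model '%s'",
                        unknown[1], key), "ibdsig_registry_error")
  }
  base[names(hyper)] <- hyper
  structure(list(key = key, hyper = base,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "model_spec")
}

#' List the full 23-entry classifier registry
#'
#' @param keys optional character vector restricting the registry to a
#'   subset of keys (order preserved).
#' @return named list of [model_spec()] objects.
#' @export
registry_list <- function(keys = NULL) {
  keys <- keys %||% .registry_keys
  bad <- setdiff(keys, .registry_keys)
  if (length(bad)) {
    stop_ibdsig(sprintf("unknown registry key '%s'", bad[1]),
                "ibdsig_registry_error")
  }
  stats::setNames(lapply(keys, model_spec), keys)
}

#' The desk-scale representative registry
#'
#' Five representative presets (bagged trees, linear SVM, coarse KNN, simple
#' tree, subspace KNN) spanning the main algorithm families, used as the
#' default registry for the shipped search fixtures.
#'
#' @return named list of [model_spec()] objects.
#' @export
registry_desk <- function() {
  registry_list(c("bagged_trees", "linear_svm", "coarse_knn",
                  "simple_tree", "subspace_knn"))
}
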