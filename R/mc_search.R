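#' Draw the random reduction step size
#'
#' Draws the number of genes to drop at one Monte Carlo iteration: a uniform
#' integer strictly less than the current subset size (and at least 1).
#' Uses the caller's RNG stream, so results are deterministic given the
#' surrounding seed.
#'
#' @param n_current current subset size (>= 2).
#' @return integer beta with `1 <= beta <= n_current - 1`.
#' @export
sample_beta <- function(n_current) {
  if (!is.numeric(n_current) || n_current < 2L) {
    stop_ibdsig("beta is only defined for subsets of at least 2 genes",
                "ibdsig_value_error")
  }
  sample.int(as.integer(n_current) - 1L, 1L)
}

#' Randomly drop beta genes from a subset
#'
#' Removes `beta` members chosen uniformly without replacement, yielding a
#' strict subset of size `length(subset) - beta`.
#'
#' @param subset a [gene_subset()].
#' @param beta integer in `[1, length(subset) - 1]`.
#' @return a [gene_subset()] with provenance `"mc_reduction"`.
#' @export
reduce_subset <- function(subset, beta) {
  stopifnot(inherits(subset, "gene_subset"))
  size <- length(subset$indices)
  beta <- as.integer(beta)
  if (beta < 1L || beta > size - 1L) {
    stop_ibdsig(sprintf("beta must lie in [1, %d]", size - 1L),
                "ibdsig_value_error")
  }
  drop <- sample.int(size, beta)
  gene_subset(subset$indices[-drop], subset$m, provenance = "mc_reduction")
}

# One reduction trajectory: iterate sample_beta + reduce_subset from the
# filtered subset until the size reaches min_size (or 2). The drawn beta is
# capped so the subset never shrinks below min_size -- the floor that keeps
# degenerate few-gene fits out of the candidate pool. Record i holds the
# subset evaluated at iteration i-1 and the beta applied to it (NA at the
# final record). Pure RNG consumer: caller controls the seed.
mc_trajectory <- function(filtered_subset, min_size = 5L) {
  stopifnot(inherits(filtered_subset, "gene_subset"),
            length(filtered_subset) >= 2L)
  min_size <- max(2L, as.integer(min_size))
  subsets <- list(filtered_subset)
  betas <- integer(0)
  repeat {
    current <- subsets[[length(subsets)]]
    size <- length(current)
    if (size <= min_size) break
    beta <- min(sample_beta(size), size - min_size)
    betas <- c(betas, beta)
    subsets[[length(subsets) + 1L]] <- reduce_subset(current, beta)
  }
  list(subsets = subsets,
       records = data.frame(
         iteration = seq_along(subsets) - 1L,
         n_genes = vapply(subsets, length, 0L),
         beta = c(betas, NA_integer_)))
}

#' Run one Monte Carlo reduction chain
#'
#' Starting from the correlation-filtered subset, repeatedly drops a random
#' number of genes (see [sample_beta()]) until the subset reaches
#' `min_size`. At every iteration, every registry spec is cross-validated on
#' the training data restricted to the current subset, and the best
#' per-iteration result (by cross-validated accuracy) is recorded.
#'
#' @param filtered_subset a [gene_subset()] (the top-q% screen output).
#' @param X_train numeric matrix, training samples x all genes.
#' @param y_train integer 0/1 training labels.
#' @param registry named list of [model_spec()]s (e.g. [registry_list()]).
#' @param cv_folds folds for [cross_validate()]; default 10.
#' @param min_size stop when the subset is this small; default 5.
#' @param seed integer seed; identical inputs and seed give identical chains.
#' @param chain_id identifier stored on the chain.
#' @return an `mc_chain`: list with `chain_id`, `records` (iteration,
#'   n_genes, beta), `subsets`, and `best` (per-iteration best
#'   `eval_result`s, each carrying its subset).
#' @export
run_chain <- function(filtered_subset, X_train, y_train,
                      registry = registry_desk(), cv_folds = 10L,
                      min_size = 5L, seed = 1L, chain_id = 1L) {
  traj <- withr::with_seed(derive_seed(seed, "trajectory"),
                           mc_trajectory(filtered_subset, min_size))
  best <- vector("list", length(traj$subsets))
  for (i in seq_along(traj$subsets)) {
    sub <- traj$subsets[[i]]
    evals <- lapply(registry, function(spec) {
      cross_validate(spec, X_train[, sub$indices, drop = FALSE], y_train,
                     k_folds = cv_folds,
                     seed = derive_seed(seed, "iter", i),
                     subset = sub)
    })
    accs <- vapply(evals, `[[`, 0, "cv_accuracy")
    best[[i]] <- evals[[which.max(accs)]]
  }
  structure(list(chain_id = chain_id, records = traj$records,
                 subsets = traj$subsets, best = best),
            class = "mc_chain")
}

.rank_candidates <- function(cands) {
  acc <- vapply(cands, `[[`, 0, "cv_accuracy")
  sizes <- vapply(cands, function(e) length(e$subset), 0L)
  keys <- vapply(cands, `[[`, "", "key")
  order(-acc, sizes, keys, method = "radix")  # radix: locale-independent
}

#' The full Monte Carlo gene-signature search
#'
#' Executes the whole discovery procedure for one task: encode labels,
#' split train/test, screen genes by point-biserial correlation on the
#' training set, keep the top q%, run `p_chains` independent random
#' reduction chains (each evaluated with the full registry under k-fold
#' cross-validation), then refit the ten best candidates (by training
#' cross-validated accuracy) on the full training set and report their
#' held-out test metrics. The test set plays no role in screening or model
#' selection.
#'
#' @param study an [expression_study()].
#' @param scheme a [label_scheme()].
#' @param q correlation-filter retention percentage; default 1.
#' @param p_chains number of independent chains; default 100.
#' @param registry named list of [model_spec()]s; default [registry_desk()].
#' @param cv_folds,min_size,top_k search parameters (defaults 10, 5, 10).
#' @param split_fraction training fraction; default 0.8.
#' @param seed integer master seed for split, chains, folds and learners.
#' @return an `mc_search_result`: list with `leaderboard` (a data frame in
#'   descending test-metric report order: n_genes, algorithm, cv_accuracy,
#'   accuracy, sensitivity, specificity), `top` (the refitted
#'   `eval_result`s with their subsets), `chains`, `filtered`
#'   (the screened subset), `profile`, `split`, and the encoded labels.
#' @export
run_search <- function(study, scheme, q = 1, p_chains = 100L,
                       registry = registry_desk(), cv_folds = 10L,
                       min_size = 5L, top_k = 10L, split_fraction = 0.8,
                       seed = 1L) {
  stopifnot(inherits(study, "expression_study"),
            inherits(scheme, "label_scheme"))
  enc <- encode_labels(study, scheme)
  split <- split_train_test(study, enc$kept, fraction = split_fraction,
                            seed = derive_seed(seed, "split"))
  y_of <- stats::setNames(enc$y, enc$kept)
  y_train <- unname(y_of[as.character(split$train)])
  y_test <- unname(y_of[as.character(split$test)])
  X_train <- t(study$expression[, split$train, drop = FALSE])
  X_test <- t(study$expression[, split$test, drop = FALSE])
  profile <- correlation_screen(study$expression[, split$train, drop = FALSE],
                                y_train)
  filtered <- top_q_filter(profile, q)
  chains <- lapply(seq_len(p_chains), function(i) {
    run_chain(filtered, X_train, y_train, registry = registry,
              cv_folds = cv_folds, min_size = min_size,
              seed = derive_seed(seed, "chain", i), chain_id = i)
  })
  cands <- unlist(lapply(chains, `[[`, "best"), recursive = FALSE)
  picked <- cands[.rank_candidates(cands)[seq_len(min(top_k, length(cands)))]]
  top <- lapply(seq_along(picked), function(i) {
    cand <- picked[[i]]
    res <- fit_and_evaluate(cand$spec, cand$subset, X_train, y_train,
                            X_test, y_test,
                            seed = derive_seed(seed, "refit", i))
    res$cv_accuracy <- cand$cv_accuracy
    res
  })
  leaderboard <- data.frame(
    n_genes = vapply(top, function(e) length(e$subset), 0L),
    algorithm = vapply(top, `[[`, "", "key"),
    cv_accuracy = vapply(top, `[[`, 0, "cv_accuracy"),
    accuracy = vapply(top, `[[`, 0, "accuracy"),
    sensitivity = vapply(top, `[[`, 0, "sensitivity"),
    specificity = vapply(top, `[[`, 0, "specificity"))
  structure(list(task = scheme$name, leaderboard = leaderboard, top = top,
                 chains = chains, filtered = filtered, profile = profile,
                 split = split, y_train = y_train, y_test = y_test,
                 seed = as.integer(seed)),
            class = "mc_search_result")
}

#' @export
print.mc_search_result <- function(x, ...) {
  cat(sprintf("<mc_search_result> task %s | %d chains | filtered %d genes\n",
              x$task, length(x$chains), length(x$filtered)))
  print(x$leaderboard, digits = 3)
  invisible(x)
}

#' Sweep multilayer perceptron depth
#'
#' Trains one network per requested depth (each `width` neurons per hidden
#' layer) on the training set, evaluates each on the test set, and returns
#' the most accurate configuration (ties go to the shallowest network).
#' Per-depth training failures are recorded and the sweep continues; it is
#' an error only if every depth fails.
#'
#' @param X_train,y_train,X_test,y_test train/test matrices (samples x
#'   genes) and 0/1 labels.
#' @param layer_values integer vector of depths to try, all >= 1.
#' @param width neurons per hidden layer; default 30.
#' @param subset optional [gene_subset()] restricting features.
#' @param seed integer seed.
#' @return list with `best_layers`, `best` (its `eval_result`) and `table`
#'   (data frame: layers, accuracy, error message if any).
#' @export
ann_layer_sweep <- function(X_train, y_train, X_test, y_test, layer_values,
                            width = 30L, subset = NULL, seed = 1L) {
  layer_values <- as.integer(layer_values)
  if (!length(layer_values) || any(layer_values < 1L)) {
    stop_ibdsig("layer_values must be a non-empty set of integers >= 1",
                "ibdsig_value_error")
  }
  rows <- lapply(layer_values, function(gamma) {
    res <- tryCatch(
      fit_and_evaluate(ann_classifier(gamma, width), subset,
                       X_train, y_train, X_test, y_test,
                       seed = derive_seed(seed, "ann", gamma)),
      error = function(e) e)
    if (inherits(res, "error")) {
      list(layers = gamma, accuracy = NA_real_, error = conditionMessage(res),
           eval = NULL)
    } else {
      list(layers = gamma, accuracy = res$accuracy, error = NA_character_,
           eval = res)
    }
  })
  tab <- data.frame(
    layers = vapply(rows, `[[`, 0L, "layers"),
    accuracy = vapply(rows, `[[`, 0, "accuracy"),
    error = vapply(rows, `[[`, "", "error"))
  ok <- which(!is.na(tab$accuracy))
  if (!length(ok)) {
    stop_ibdsig("every network depth failed to train", "ibdsig_train_error")
  }
  best_i <- ok[order(-tab$accuracy[ok], tab$layers[ok])][1]
  list(best_layers = tab$layers[best_i], best = rows[[best_i]]$eval,
       table = tab)
}

#' Select the final model
#'
#' Compares the best Monte Carlo search result with the best network from
#' the depth sweep and returns the more accurate one (test accuracy). On an
#' exact tie the non-network result wins -- it is the interpretable,
#' fewer-parameter model.
#'
#' @param search an `mc_search_result` (or its top `eval_result`).
#' @param ann_best the list returned by [ann_layer_sweep()].
#' @return list with `source` (`"ml"` or `"ann"`), `accuracy` and `result`.
#' @export
select_best <- function(search, ann_best) {
  ml <- if (inherits(search, "mc_search_result")) {
    if (!length(search$top)) {
      stop_ibdsig("search produced no candidates", "ibdsig_value_error")
    }
    search$top[[1L]]
  } else search
  ann <- ann_best$best
  if (is.null(ml) || is.null(ann)) {
    stop_ibdsig("both a search result and a sweep result are required",
                "ibdsig_value_error")
  }
  if (ann$accuracy > ml$accuracy) {
    list(source = "ann", accuracy = ann$accuracy, result = ann)
  } else {
    list(source = "ml", accuracy = ml$accuracy, result = ml)
  }
}
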