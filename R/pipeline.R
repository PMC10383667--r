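#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end discovery run. Defaults mirror the
#' full study protocol (q = 1, 100 chains, 10-fold CV, 80/20 split, full
#' 23-model registry); pass `registry_keys` and smaller `p_chains` for
#' desk-scale runs. Exactly one of `input` (a study TSV path) or
#' `simulation` (a [simulation_config()]) must be supplied.
#'
#' @param task `"control_vs_ibd"`, `"uc_vs_cd"` or `"both"`.
#' @param q correlation-filter retention percentage.
#' @param p_chains number of Monte Carlo chains per task.
#' @param cv_folds cross-validation folds.
#' @param registry_keys registry keys to use; `NULL` = all 23.
#' @param min_size chain stopping size.
#' @param ann_layers depth grid for the network sweep; `NULL` disables it.
#' @param lasso run the lasso comparison arm (default `TRUE`).
#' @param split_fraction training fraction.
#' @param seed master seed.
#' @param input path to a study TSV, or `NULL`.
#' @param simulation a [simulation_config()], or `NULL`.
#' @param out_dir output directory for [run_pipeline()] artifacts; `NULL`
#'   keeps results in memory only.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(task = c("both", "control_vs_ibd", "uc_vs_cd"),
                            q = 1, p_chains = 100L, cv_folds = 10L,
                            registry_keys = NULL, min_size = 5L,
                            ann_layers = c(1L, 2L, 5L, 10L, 20L, 50L),
                            lasso = TRUE, split_fraction = 0.8, seed = 1L,
                            input = NULL, simulation = NULL,
                            out_dir = NULL) {
  task <- match.arg(task)
  if (is.null(input) == is.null(simulation)) {
    stop_ibdsig("supply exactly one of `input` and `simulation`",
                "ibdsig_value_error")
  }
  if (!is.null(simulation)) stopifnot(inherits(simulation, "simulation_config"))
  stopifnot(q > 0, q <= 100, p_chains >= 1L, cv_folds >= 2L, min_size >= 2L,
            split_fraction > 0, split_fraction < 1)
  if (!is.null(ann_layers)) stopifnot(all(ann_layers >= 1L))
  if (!is.null(registry_keys)) registry_list(registry_keys)  # validates
  structure(list(task = task, q = q, p_chains = as.integer(p_chains),
                 cv_folds = as.integer(cv_folds),
                 registry_keys = registry_keys,
                 min_size = as.integer(min_size),
                 ann_layers = if (is.null(ann_layers)) NULL
                              else as.integer(ann_layers),
                 lasso = isTRUE(lasso), split_fraction = split_fraction,
                 seed = as.integer(seed), input = input,
                 simulation = simulation, out_dir = out_dir),
            class = "pipeline_config")
}

.pipeline_tasks <- function(task) {
  if (task == "both") c("control_vs_ibd", "uc_vs_cd") else task
}

# Evaluate every registry spec on the lasso-selected genes and report the
# top test-set rows -- the comparison-arm leaderboard.
.lasso_arm <- function(study, scheme, config, registry) {
  enc <- encode_labels(study, scheme)
  split <- split_train_test(study, enc$kept, fraction = config$split_fraction,
                            seed = derive_seed(config$seed, "split"))
  y_of <- stats::setNames(enc$y, enc$kept)
  y_train <- unname(y_of[as.character(split$train)])
  y_test <- unname(y_of[as.character(split$test)])
  X_train <- t(study$expression[, split$train, drop = FALSE])
  X_test <- t(study$expression[, split$test, drop = FALSE])
  subset <- lasso_select(study$expression[, split$train, drop = FALSE],
                         y_train, seed = derive_seed(config$seed, "lasso"))
  if (!length(subset$indices)) {
    return(list(subset = subset, leaderboard = NULL))
  }
  evals <- lapply(registry, function(spec) {
    fit_and_evaluate(spec, subset, X_train, y_train, X_test, y_test,
                     seed = derive_seed(config$seed, "lasso", spec$key))
  })
  ord <- order(-vapply(evals, `[[`, 0, "accuracy"),
               vapply(evals, `[[`, "", "key"), method = "radix")
  evals <- evals[ord[seq_len(min(10L, length(evals)))]]
  list(subset = subset,
       leaderboard = data.frame(
         algorithm = vapply(evals, `[[`, "", "key"),
         n_genes = length(subset$indices),
         accuracy = vapply(evals, `[[`, 0, "accuracy"),
         sensitivity = vapply(evals, `[[`, 0, "sensitivity"),
         specificity = vapply(evals, `[[`, 0, "specificity")))
}

#' Run the full discovery pipeline
#'
#' Loads or simulates the study, then per task: runs the Monte Carlo search
#' ([run_search()]), the network depth sweep ([ann_layer_sweep()]) on the
#' screened gene set, the final selection ([select_best()]), and optionally
#' the lasso arm. If `out_dir` is set, writes per task: the leaderboard CSV,
#' a per-chain ledger CSV (chain, iteration, n_genes, beta, best algorithm,
#' cv accuracy), the winning gene list, the sweep table and the lasso
#' leaderboard, plus a JSON run manifest (config, seed, package version,
#' per-stage wall times).
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result`: list with `study`, per-task results
#'   (`search`, `ann`, `final`, `lasso`), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  study <- if (!is.null(config$input)) read_study(config$input)
           else generate_study(config$simulation)$study
  timings$load <- proc.time()[["elapsed"]] - t0
  registry <- registry_list(config$registry_keys)
  tasks <- .pipeline_tasks(config$task)
  results <- list()
  for (task in tasks) {
    tick <- proc.time()[["elapsed"]]
    scheme <- label_scheme(task)
    search <- run_search(study, scheme, q = config$q,
                         p_chains = config$p_chains, registry = registry,
                         cv_folds = config$cv_folds,
                         min_size = config$min_size,
                         split_fraction = config$split_fraction,
                         seed = derive_seed(config$seed, task))
    ann <- NULL
    final <- NULL
    if (!is.null(config$ann_layers)) {
      X_train <- t(study$expression[, search$split$train, drop = FALSE])
      X_test <- t(study$expression[, search$split$test, drop = FALSE])
      ann <- ann_layer_sweep(X_train, search$y_train, X_test, search$y_test,
                             layer_values = config$ann_layers,
                             subset = search$filtered,
                             seed = derive_seed(config$seed, task, "ann"))
      final <- select_best(search, ann)
    }
    lasso <- if (config$lasso) {
      .lasso_arm(study, scheme, config, registry)
    }
    timings[[task]] <- proc.time()[["elapsed"]] - tick
    results[[task]] <- list(search = search, ann = ann, final = final,
                            lasso = lasso)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ibdsig")),
    seed = config$seed,
    config = .config_manifest(config),
    timings_seconds = lapply(timings, round, 2))
  out <- structure(list(study = study, tasks = results, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) .write_pipeline_outputs(out, config)
  out
}

.config_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$simulation <- if (!is.null(cfg$simulation)) {
    sim <- unclass(cfg$simulation)
    sim$class_proportions <- as.list(sim$class_proportions)
    if (length(sim$effect_size) > 1L) sim$effect_size <- as.list(sim$effect_size)
    sim
  }
  cfg
}

.chain_ledger <- function(chains) {
  do.call(rbind, lapply(chains, function(ch) {
    data.frame(chain = ch$chain_id, ch$records,
               best_algorithm = vapply(ch$best, `[[`, "", "key"),
               cv_accuracy = vapply(ch$best, `[[`, 0, "cv_accuracy"))
  }))
}

.write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (task in names(result$tasks)) {
    res <- result$tasks[[task]]
    prefix <- file.path(config$out_dir, task)
    utils::write.csv(res$search$leaderboard,
                     paste0(prefix, "_leaderboard.csv"), row.names = FALSE)
    utils::write.csv(.chain_ledger(res$search$chains),
                     paste0(prefix, "_chains.csv"), row.names = FALSE)
    win <- res$search$top[[1L]]
    writeLines(result$study$gene_ids[win$subset$indices],
               paste0(prefix, "_winning_genes.txt"))
    if (!is.null(res$ann)) {
      utils::write.csv(res$ann$table, paste0(prefix, "_ann_sweep.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$lasso) && !is.null(res$lasso$leaderboard)) {
      utils::write.csv(res$lasso$leaderboard,
                       paste0(prefix, "_lasso_leaderboard.csv"),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(result$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(config$out_dir)
}

.md_table <- function(df) {
  fmt <- function(x) if (is.numeric(x)) sprintf("%.3f", x) else as.character(x)
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

#' Render a markdown report of a pipeline run
#'
#' Produces a human-readable summary: per task, the top-ten Monte Carlo
#' leaderboard, the network sweep outcome, the final selection and (when
#' run) the lasso-arm leaderboard. Regeneration from the same result is
#' byte-identical.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param path optional file to write the report to.
#' @return the report lines, invisibly if `path` is given.
#' @export
render_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  lines <- c("# Gene-signature discovery report", "")
  for (task in names(result$tasks)) {
    res <- result$tasks[[task]]
    lines <- c(lines, sprintf("## Task: %s", task), "",
               "### Monte Carlo search -- top models", "",
               .md_table(res$search$leaderboard), "")
    if (!is.null(res$ann)) {
      lines <- c(lines,
                 sprintf("### Network depth sweep: best %d layers, accuracy %.3f",
                         res$ann$best_layers, res$ann$best$accuracy), "")
    }
    if (!is.null(res$final)) {
      lines <- c(lines,
                 sprintf("### Final selection: %s (test accuracy %.3f)",
                         res$final$source, res$final$accuracy), "")
    }
    if (!is.null(res$lasso) && !is.null(res$lasso$leaderboard)) {
      lines <- c(lines,
                 sprintf("### Lasso arm (%d genes selected)",
                         length(res$lasso$subset$indices)), "",
                 .md_table(res$lasso$leaderboard), "")
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
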