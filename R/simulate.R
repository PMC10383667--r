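#' Simulation configuration for synthetic expression studies
#'
#' Describes a synthetic cohort with known ground truth: per-gene Gaussian
#' expression with class-conditional mean shifts on a chosen contrast for a
#' planted subset of "informative" genes, and covariates (age, sex, biopsy
#' region) drawn to match the structure of a large adult IBD cohort
#' (class mix about 18.5% control / 35% UC / 46.5% CD, ages 19-82 with mean
#' near 45, seven biopsy areas at their observed frequencies).
#'
#' @param n_samples number of samples (columns); default 300.
#' @param n_genes number of genes (rows); default 500.
#' @param class_proportions named proportions for control/UC/CD, summing to
#'   1; defaults to the cohort mix above.
#' @param n_informative number of planted informative genes; default 25.
#' @param effect_size class-mean shift in units of `baseline_sd`. A scalar,
#'   or for `informative_task = "both"` a length-2 vector giving the
#'   control-vs-IBD and UC-vs-CD effects respectively.
#' @param informative_task contrast the planted genes separate:
#'   `"control_vs_ibd"`, `"uc_vs_cd"` or `"both"` (informative genes split
#'   evenly between the two contrasts).
#' @param baseline_mean,baseline_sd Gaussian parameters for null genes;
#'   defaults 8 and 2 (log2-scale-like expression).
#' @param expression_model `"gaussian"` (default) or `"lognormal"` (the
#'   Gaussian model exponentiated, for skewed positive values).
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @return a validated `simulation_config`.
#' @export
simulation_config <- function(n_samples = 300L,
                              n_genes = 500L,
                              class_proportions = c(control = 461, UC = 872,
                                                    CD = 1157) / 2490,
                              n_informative = 25L,
                              effect_size = 1.5,
                              informative_task = c("control_vs_ibd",
                                                   "uc_vs_cd", "both"),
                              baseline_mean = 8,
                              baseline_sd = 2,
                              expression_model = c("gaussian", "lognormal"),
                              seed = 1L) {
  informative_task <- match.arg(informative_task)
  expression_model <- match.arg(expression_model)
  n_samples <- as.integer(n_samples)
  n_genes <- as.integer(n_genes)
  n_informative <- as.integer(n_informative)
  stopifnot(n_samples >= 2L, n_genes >= 1L,
            n_informative >= 0L, n_informative <= n_genes,
            baseline_sd > 0)
  if (length(class_proportions) != 3L ||
      abs(sum(class_proportions) - 1) > 1e-9 || any(class_proportions < 0)) {
    stop_ibdsig("class_proportions must be 3 non-negative values summing to 1",
                "ibdsig_value_error")
  }
  names(class_proportions) <- ibd_classes()
  if (informative_task == "both") {
    if (length(effect_size) == 1L) effect_size <- rep(effect_size, 2L)
    stopifnot(length(effect_size) == 2L)
    names(effect_size) <- c("control_vs_ibd", "uc_vs_cd")
  } else {
    stopifnot(length(effect_size) == 1L)
  }
  stopifnot(all(effect_size >= 0))
  structure(
    list(n_samples = n_samples, n_genes = n_genes,
         class_proportions = class_proportions,
         n_informative = n_informative, effect_size = effect_size,
         informative_task = informative_task,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         expression_model = expression_model, seed = as.integer(seed)),
    class = "simulation_config")
}

# Age weights: discretized normal (mean 45, sd 14) on 19..82, giving a
# right-truncated adult age distribution with mean close to 45.
.age_weights <- function() {
  ages <- 19:82
  w <- stats::dnorm(ages, mean = 45, sd = 14)
  list(ages = ages, w = w / sum(w))
}

# Observed biopsy-area frequencies in the emulated cohort.
.region_weights <- function() {
  c(Rectum = 904, `Left colon` = 180, `Right colon` = 252, Ileum = 672,
    Transverse = 90, Sigmoid = 163, Cecum = 229) / 2490
}

#' Generate a synthetic expression study with known ground truth
#'
#' Class counts follow the configured proportions by largest-remainder
#' rounding. Null genes are i.i.d. Gaussian; each planted gene's mean is
#' shifted by `effect_size * baseline_sd` for the positive group of its
#' contrast (IBD samples for control-vs-IBD; CD samples for UC-vs-CD).
#' With `effect_size = 0` the matrix is exchangeable across class labels.
#' Covariates are generated independently of class, so the planted genes are
#' the only true signal.
#'
#' @param config a [simulation_config()].
#' @return list with `study` (an [expression_study()]) and `truth`, a list
#'   holding `informative_gene_ids`, a per-gene `means` data frame
#'   (gene_id, contrast, mean_class0, mean_class1) and the raw label vector.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_samples
  m <- config$n_genes
  counts <- alloc_largest_remainder(config$class_proportions, n)
  infeasible <- config$class_proportions > 0 & counts == 0L
  if (any(infeasible)) {
    stop_ibdsig(sprintf(
      "class '%s' has positive proportion but 0 samples after rounding; increase n_samples",
      ibd_classes()[which(infeasible)[1]]), "ibdsig_value_error")
  }
  out <- withr::with_seed(config$seed, {
    labels <- sample(rep(ibd_classes(), counts))
    aw <- .age_weights()
    age <- sample(aw$ages, n, replace = TRUE, prob = aw$w)
    sex <- stats::rbinom(n, 1L, 1316 / 2490)
    rw <- .region_weights()
    region <- sample(names(rw), n, replace = TRUE, prob = rw)
    expr <- matrix(stats::rnorm(as.double(m) * n, config$baseline_mean,
                                config$baseline_sd), nrow = m, ncol = n)
    gene_ids <- sprintf("G%05d", seq_len(m))
    informative <- if (config$n_informative > 0L) {
      sort(sample.int(m, config$n_informative))
    } else integer(0)
    contrast_of <- if (config$informative_task == "both") {
      half <- ceiling(length(informative) / 2)
      rep(c("control_vs_ibd", "uc_vs_cd"),
          c(half, length(informative) - half))
    } else {
      rep(config$informative_task, length(informative))
    }
    effect_of <- function(contrast) {
      if (config$informative_task == "both") config$effect_size[[contrast]]
      else config$effect_size
    }
    means <- NULL
    if (length(informative)) {
      shift <- vapply(contrast_of, effect_of, 0) * config$baseline_sd
      positive <- list(
        control_vs_ibd = labels %in% c("UC", "CD"),
        uc_vs_cd = labels == "CD")
      for (i in seq_along(informative)) {
        pos <- positive[[contrast_of[i]]]
        expr[informative[i], pos] <- expr[informative[i], pos] + shift[i]
      }
      means <- data.frame(
        gene_id = gene_ids[informative],
        contrast = contrast_of,
        mean_class0 = config$baseline_mean,
        mean_class1 = config$baseline_mean + shift,
        stringsAsFactors = FALSE)
    }
    if (config$expression_model == "lognormal") expr <- exp(expr / 4)
    list(labels = labels, age = age, sex = sex, region = region,
         expr = expr, gene_ids = gene_ids, informative = informative,
         means = means)
  })
  study <- expression_study(
    expression = out$expr, labels = out$labels, age = out$age,
    sex = out$sex, region = out$region, gene_ids = out$gene_ids,
    sample_ids = sprintf("S%04d", seq_len(n)))
  truth <- list(
    informative_gene_ids = out$gene_ids[out$informative],
    informative_idx = out$informative,
    means = out$means,
    labels = out$labels)
  list(study = study, truth = truth)
}

#' Write a reproducible fixture bundle
#'
#' Generates the study described by `config` and writes three files to
#' `out_dir`: `study.tsv` (the [write_study()] dialect), `ground_truth.csv`
#' (gene_id, contrast, mean_class0, mean_class1) and `config.yaml`, an echo
#' of the configuration. Regenerating from the echoed config reproduces the
#' study file byte-identically.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory, created if needed.
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_study(config)
  paths <- c(study = file.path(out_dir, "study.tsv"),
             truth = file.path(out_dir, "ground_truth.csv"),
             config = file.path(out_dir, "config.yaml"))
  write_study(gen$study, paths[["study"]])
  truth_df <- gen$truth$means %||%
    data.frame(gene_id = character(0), contrast = character(0),
               mean_class0 = numeric(0), mean_class1 = numeric(0))
  utils::write.csv(truth_df, paths[["truth"]], row.names = FALSE)
  cfg <- unclass(config)
  cfg$class_proportions <- as.list(cfg$class_proportions)
  if (length(cfg$effect_size) > 1L) cfg$effect_size <- as.list(cfg$effect_size)
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}

#' Rebuild a simulation config from its YAML echo
#'
#' @param path path to a `config.yaml` written by [write_fixture_bundle()].
#' @return a [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  simulation_config(
    n_samples = raw$n_samples, n_genes = raw$n_genes,
    class_proportions = unlist(raw$class_proportions),
    n_informative = raw$n_informative,
    effect_size = unlist(raw$effect_size),
    informative_task = raw$informative_task,
    baseline_mean = raw$baseline_mean, baseline_sd = raw$baseline_sd,
    expression_model = raw$expression_model, seed = raw$seed)
}
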