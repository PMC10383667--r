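#' @title Labeled expression studies
#' @description
#' An `expression_study` holds a genes x samples expression matrix together
#' with the per-sample covariates used throughout the pipeline: the raw
#' disease class (control / UC / CD), age in years, sex (female = 0,
#' male = 1) and the biopsy region. Samples are columns, genes are rows --
#' the layout the pipeline consumes and serializes.
#' @name expression_study
NULL

#' Disease classes and biopsy regions
#'
#' The three raw disease classes and the seven biopsy areas recognised by
#' the data model. Regions are encoded internally as integers `0:6` in this
#' fixed order.
#'
#' @export
ibd_classes <- function() c("control", "UC", "CD")

#' @rdname ibd_classes
#' @export
ibd_regions <- function() {
  c("Rectum", "Left colon", "Right colon", "Ileum",
    "Transverse", "Sigmoid", "Cecum")
}

#' Construct and validate an expression study
#'
#' @param expression numeric matrix, genes in rows, samples in columns. All
#'   values must be finite.
#' @param labels character vector of raw classes, one per sample, each one of
#'   `ibd_classes()`.
#' @param age positive integer ages in years, one per sample.
#' @param sex integer vector of 0 (female) / 1 (male), one per sample.
#' @param region character vector of biopsy areas, one per sample, each one
#'   of `ibd_regions()`.
#' @param gene_ids,sample_ids unique identifier strings; default to the
#'   dimnames of `expression`.
#' @return an object of class `expression_study`.
#' @export
expression_study <- function(expression, labels, age, sex, region,
                             gene_ids = rownames(expression),
                             sample_ids = colnames(expression)) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  m <- nrow(expression)
  n <- ncol(expression)
  if (m < 1L || n < 2L) {
    stop_ibdsig("an expression study needs at least 1 gene and 2 samples",
                "ibdsig_dim_error")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("G%05d", seq_len(m))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  if (anyDuplicated(gene_ids)) {
    stop_ibdsig(sprintf("duplicated gene id: %s",
                        gene_ids[duplicated(gene_ids)][1]),
                "ibdsig_duplicate_id_error")
  }
  if (anyDuplicated(sample_ids)) {
    stop_ibdsig(sprintf("duplicated sample id: %s",
                        sample_ids[duplicated(sample_ids)][1]),
                "ibdsig_duplicate_id_error")
  }
  if (length(gene_ids) != m || length(sample_ids) != n ||
      length(labels) != n || length(age) != n || length(sex) != n ||
      length(region) != n) {
    stop_ibdsig("covariate lengths must match the number of samples",
                "ibdsig_dim_error")
  }
  if (!all(is.finite(expression))) {
    stop_ibdsig("expression values must all be finite", "ibdsig_value_error")
  }
  bad <- which(!labels %in% ibd_classes())
  if (length(bad)) {
    stop_ibdsig(sprintf("unknown class label '%s' for sample '%s'",
                        labels[bad[1]], sample_ids[bad[1]]),
                "ibdsig_label_error")
  }
  bad <- which(!region %in% ibd_regions())
  if (length(bad)) {
    stop_ibdsig(sprintf("unknown biopsy region '%s' for sample '%s'",
                        region[bad[1]], sample_ids[bad[1]]),
                "ibdsig_region_error")
  }
  age <- as.integer(age)
  if (any(is.na(age)) || any(age <= 0L)) {
    stop_ibdsig("ages must be positive integers", "ibdsig_value_error")
  }
  sex <- as.integer(sex)
  if (any(is.na(sex)) || !all(sex %in% c(0L, 1L))) {
    stop_ibdsig("sex codes must be 0 (female) or 1 (male)",
                "ibdsig_value_error")
  }
  dimnames(expression) <- list(gene_ids, sample_ids)
  structure(
    list(expression = expression,
         labels = as.character(labels),
         age = age, sex = sex, region = as.character(region),
         gene_ids = as.character(gene_ids),
         sample_ids = as.character(sample_ids)),
    class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %d genes x %d samples\n",
              nrow(x$expression), ncol(x$expression)))
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$labels)),
                                  table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
n_genes <- function(study) UseMethod("n_genes")
#' @export
n_genes.expression_study <- function(study) nrow(study$expression)
#' @export
n_samples <- function(study) UseMethod("n_samples")
#' @export
n_samples.expression_study <- function(study) ncol(study$expression)

#' Label schemes for the two classification tasks
#'
#' `control_vs_ibd` codes control as 0 and both IBD forms (UC, CD) as 1.
#' `uc_vs_cd` codes UC as 0 and CD as 1 and excludes controls entirely.
#'
#' @param name one of `"control_vs_ibd"`, `"uc_vs_cd"`.
#' @return a `label_scheme`: a named mapping from raw class to 0/1, with
#'   `NA` marking excluded classes.
#' @export
label_scheme <- function(name = c("control_vs_ibd", "uc_vs_cd")) {
  name <- match.arg(name)
  mapping <- switch(name,
    control_vs_ibd = c(control = 0L, UC = 1L, CD = 1L),
    uc_vs_cd = c(control = NA_integer_, UC = 0L, CD = 1L))
  structure(list(name = name, mapping = mapping), class = "label_scheme")
}

#' Encode raw class labels as a binary vector
#'
#' Applies a [label_scheme()] to a study, dropping samples the scheme
#' excludes (controls, in the UC-vs-CD task).
#'
#' @param study an [expression_study()].
#' @param scheme a [label_scheme()].
#' @return list with `y` (integer 0/1 vector over kept samples, in sample
#'   order) and `kept` (column indices of the kept samples).
#' @export
encode_labels <- function(study, scheme) {
  stopifnot(inherits(study, "expression_study"),
            inherits(scheme, "label_scheme"))
  unknown <- which(!study$labels %in% names(scheme$mapping))
  if (length(unknown)) {
    stop_ibdsig(sprintf("unknown raw label '%s' for sample '%s'",
                        study$labels[unknown[1]],
                        study$sample_ids[unknown[1]]),
                "ibdsig_label_error")
  }
  coded <- unname(scheme$mapping[study$labels])
  kept <- which(!is.na(coded))
  y <- coded[kept]
  if (length(unique(y)) < 2L) {
    stop_ibdsig(sprintf(
      "scheme '%s' leaves a single class among kept samples; classification undefined",
      scheme$name), "ibdsig_single_class_error")
  }
  list(y = y, kept = kept)
}

#' Randomized train/test split
#'
#' Partitions the kept samples into a training and a testing set holding
#' approximately `fraction` and `1 - fraction` of the samples. The training
#' size is exactly `round(fraction * n)` (half away from zero). By default
#' the split is stratified by class so both halves contain every class;
#' `stratify = FALSE` restores a simple random split.
#'
#' @param study an [expression_study()].
#' @param kept integer indices of eligible samples (e.g. from
#'   [encode_labels()]). Defaults to all samples.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed; the same inputs and seed reproduce the split.
#' @param stratify stratify by raw class label (default `TRUE`).
#' @return list with sorted integer vectors `train` and `test` (indices into
#'   the study's sample columns, disjoint, union = `kept`) and `seed`.
#' @export
split_train_test <- function(study, kept = seq_len(n_samples(study)),
                             fraction = 0.8, seed = 1L, stratify = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop_ibdsig("fraction must lie strictly between 0 and 1",
                "ibdsig_value_error")
  }
  kept <- as.integer(kept)
  n <- length(kept)
  if (n < 2L) {
    stop_ibdsig("need at least 2 kept samples to split", "ibdsig_dim_error")
  }
  n_train <- as.integer(round_half_away(fraction * n))
  n_train <- max(1L, min(n - 1L, n_train))
  train <- withr::with_seed(as.integer(seed), {
    if (stratify) {
      cls <- study$labels[kept]
      # fixed level order keeps the split independent of the collation locale
      groups <- split(kept, factor(cls, levels = intersect(ibd_classes(),
                                                           unique(cls))))
      counts <- lengths(groups)
      per <- alloc_largest_remainder(counts, n_train)
      # best-effort: give every class >= 2 samples a seat in both halves,
      # without breaking the exact train size (infeasible when there are
      # more classes than test slots; the allocation then stays as-is)
      repeat {
        starved <- which(per == 0L & counts >= 2L)
        donors <- which(per >= 2L)
        if (!length(starved) || !length(donors)) break
        per[starved[1L]] <- 1L
        per[donors[1L]] <- per[donors[1L]] - 1L
      }
      repeat {
        full <- which(per == counts & counts >= 2L)
        takers <- which(counts - per >= 2L)
        if (!length(full) || !length(takers)) break
        per[full[1L]] <- per[full[1L]] - 1L
        per[takers[1L]] <- per[takers[1L]] + 1L
      }
      unlist(Map(function(g, k) if (k > 0L) sample(g, k) else integer(0),
                 groups, per), use.names = FALSE)
    } else {
      sample(kept, n_train)
    }
  })
  train <- sort(as.integer(train))
  structure(list(train = train, test = sort(setdiff(kept, train)),
                 seed = as.integer(seed)),
            class = "split_indices")
}

#' Read and write studies as TSV
#'
#' Serializes an [expression_study()] as a UTF-8 tab-separated file with
#' samples as columns. The first column holds row names; the first four data
#' rows are, in fixed order, `label` (raw class), `age`, `sex` (0/1) and
#' `region`, followed by one row per gene. Numeric values are written with
#' 17 significant digits so that write-then-read reproduces the study
#' bit-identically.
#'
#' @param study an [expression_study()].
#' @param path file path.
#' @return `write_study` returns `path` invisibly; `read_study` returns an
#'   [expression_study()].
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "expression_study"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  wline <- function(...) {
    writeLines(paste(c(...), collapse = "\t"), con, sep = "\n",
               useBytes = TRUE)
  }
  wline("id", study$sample_ids)
  wline("label", study$labels)
  wline("age", as.character(study$age))
  wline("sex", as.character(study$sex))
  wline("region", study$region)
  num <- matrix(sprintf("%.17g", study$expression), nrow = nrow(study$expression))
  body <- paste(study$gene_ids, apply(num, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(body, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_study
#' @export
read_study <- function(path) {
  if (!file.exists(path)) {
    stop_ibdsig(sprintf("no such study file: %s", path), "ibdsig_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 6L) {
    stop_ibdsig("study file must contain header rows and at least one gene",
                "ibdsig_parse_error")
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    stop_ibdsig(sprintf("ragged study file: line %d has %d fields, expected %d",
                        which(widths != widths[1])[1],
                        widths[widths != widths[1]][1], widths[1]),
                "ibdsig_parse_error")
  }
  header <- cells[[1]]
  sample_ids <- header[-1]
  rows <- lapply(cells[-1], function(x) x)
  row_names <- vapply(rows, `[[`, "", 1L)
  expected <- c("label", "age", "sex", "region")
  if (!identical(row_names[1:4], expected)) {
    stop_ibdsig(sprintf(
      "header rows must be %s in order; found %s",
      paste(expected, collapse = ", "), paste(row_names[1:4], collapse = ", ")),
      "ibdsig_parse_error")
  }
  get_row <- function(i) rows[[i]][-1]
  parse_num <- function(vals, rowname) {
    out <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(out) & !is.na(vals))
    if (length(bad)) {
      stop_ibdsig(sprintf("non-numeric value '%s' in row '%s', column %d",
                          vals[bad[1]], rowname, bad[1]),
                  "ibdsig_parse_error")
    }
    out
  }
  gene_rows <- rows[-(1:4)]
  gene_ids <- vapply(gene_rows, `[[`, "", 1L)
  expr <- t(vapply(seq_along(gene_rows),
                   function(i) parse_num(gene_rows[[i]][-1], gene_ids[i]),
                   numeric(length(sample_ids))))
  expression_study(
    expression = expr,
    labels = get_row(1L),
    age = parse_num(get_row(2L), "age"),
    sex = parse_num(get_row(3L), "sex"),
    region = get_row(4L),
    gene_ids = gene_ids,
    sample_ids = sample_ids)
}
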