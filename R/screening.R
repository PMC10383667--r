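#' Gene subsets
#'
#' An ordered, duplicate-free set of gene row indices with a provenance tag
#' recording how it was produced.
#'
#' @param indices integer gene indices (1-based).
#' @param m total number of genes the indices refer to.
#' @param provenance one of `"correlation_filter"`, `"mc_reduction"`,
#'   `"lasso"`, `"manual"`.
#' @param q,lambda the retention percentage or penalty used, when applicable.
#' @return a `gene_subset`.
#' @export
gene_subset <- function(indices, m,
                        provenance = c("manual", "correlation_filter",
                                       "mc_reduction", "lasso"),
                        q = NULL, lambda = NULL) {
  provenance <- match.arg(provenance)
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) {
    stop_ibdsig("gene subset contains duplicate indices",
                "ibdsig_value_error")
  }
  if (length(indices) && (min(indices) < 1L || max(indices) > m)) {
    stop_ibdsig("gene subset indices out of range", "ibdsig_value_error")
  }
  structure(list(indices = sort(indices), m = as.integer(m),
                 provenance = provenance, q = q, lambda = lambda),
            class = "gene_subset")
}

#' @export
length.gene_subset <- function(x) length(x$indices)

#' @export
print.gene_subset <- function(x, ...) {
  cat(sprintf("<gene_subset> %d of %d genes (%s)\n",
              length(x$indices), x$m, x$provenance))
  invisible(x)
}

#' Point-biserial correlation of every gene with a binary label
#'
#' Computes, for each gene row of the training matrix, the Pearson
#' correlation with the 0/1 class label (the point-biserial correlation).
#' Genes with zero variance get correlation 0 by convention, so a constant
#' gene can never be ranked as informative.
#'
#' @param train_expression numeric matrix, genes x samples (training
#'   samples only -- the screen must not see the test set).
#' @param labels integer 0/1 vector, one per column.
#' @return a `correlation_profile`: list with `correlation` (length-m vector
#'   in `[-1, 1]`) and `n_samples`.
#' @export
correlation_screen <- function(train_expression, labels) {
  train_expression <- as.matrix(train_expression)
  labels <- as.integer(labels)
  if (ncol(train_expression) != length(labels)) {
    stop_ibdsig("label length must equal the number of sample columns",
                "ibdsig_dim_error")
  }
  if (length(labels) < 2L) {
    stop_ibdsig("need at least 2 samples to correlate", "ibdsig_dim_error")
  }
  if (length(unique(labels)) < 2L) {
    stop_ibdsig("labels contain a single class; correlation undefined",
                "ibdsig_single_class_error")
  }
  r <- suppressWarnings(
    as.vector(stats::cor(t(train_expression), labels)))
  r[!is.finite(r)] <- 0
  structure(list(correlation = r, n_samples = length(labels)),
            class = "correlation_profile")
}

#' Retain the top q% most label-correlated genes
#'
#' Keeps the `max(1, floor(q/100 * m))` genes with the largest absolute
#' correlation; ties are broken by ascending gene index so the filter is
#' deterministic. At the cohort scale of 56,632 genes, `q = 1` retains 566.
#'
#' @param profile a [correlation_screen()] result, or a bare numeric vector
#'   of correlations.
#' @param q retention percentage in (0, 100].
#' @return a [gene_subset()] with provenance `"correlation_filter"`,
#'   indices in ascending order.
#' @export
top_q_filter <- function(profile, q) {
  r <- if (inherits(profile, "correlation_profile")) profile$correlation
       else as.numeric(profile)
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 100) {
    stop_ibdsig("q must lie in (0, 100]", "ibdsig_value_error")
  }
  m <- length(r)
  size <- max(1L, as.integer(floor(q / 100 * m)))
  picked <- order(-abs(r), seq_len(m))[seq_len(size)]
  gene_subset(picked, m, provenance = "correlation_filter", q = q)
}

#' Lasso gene selection
#'
#' Fits an L1-penalized logistic regression of the binary label on all
#' genes (features standardized internally; this is the `glmnet` path
#' algorithm) and returns the genes with nonzero coefficients at the chosen
#' penalty. By default the penalty is picked by seeded 10-fold
#' cross-validated deviance at the one-standard-error rule, the
#' conservative choice that keeps the selected set small under the null.
#'
#' @param train_expression numeric matrix, genes x samples.
#' @param labels integer 0/1 vector, one per column.
#' @param lambda `"lambda.1se"` (default), `"lambda.min"`, or a fixed
#'   numeric penalty.
#' @param nfolds folds for the cross-validated penalty choice; default 10.
#' @param seed integer seed controlling the fold assignment.
#' @return a [gene_subset()] with provenance `"lasso"` and the penalty used
#'   in `$lambda`; the selected coefficients are attached as
#'   `attr(, "coefficients")` (named, original scale).
#' @export
lasso_select <- function(train_expression, labels, lambda = "lambda.1se",
                         nfolds = 10L, seed = 1L) {
  X <- t(as.matrix(train_expression))
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) {
    stop_ibdsig("labels contain a single class", "ibdsig_single_class_error")
  }
  m <- ncol(X)
  fit <- withr::with_seed(as.integer(seed), {
    if (is.character(lambda)) {
      foldid <- make_folds(y, k = nfolds, seed = derive_seed(seed, "lasso"),
                           stratify = TRUE)
      cv <- glmnet::cv.glmnet(X, y, family = "binomial", foldid = foldid,
                              standardize = TRUE)
      list(model = cv$glmnet.fit, s = cv[[lambda]])
    } else {
      model <- glmnet::glmnet(X, y, family = "binomial", standardize = TRUE)
      list(model = model, s = as.numeric(lambda))
    }
  })
  beta <- stats::coef(fit$model, s = fit$s)[-1, 1]
  idx <- which(beta != 0)
  subset <- gene_subset(idx, m, provenance = "lasso", lambda = fit$s)
  attr(subset, "coefficients") <- beta[idx]
  subset
}
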