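# Small deterministic fixtures built in code.

# A hand-written 3-gene x 4-sample study covering all covariate fields.
tiny_study <- function() {
  expression_study(
    expression = matrix(c(1.5, 2.5, 3.5, 4.5,
                          10, 20, 30, 40,
                          0.1, 0.2, 0.3, 0.4), nrow = 3, byrow = TRUE),
    labels = c("UC", "control", "CD", "control"),
    age = c(47, 52, 61, 33),
    sex = c(0, 1, 1, 0),
    region = c("Rectum", "Ileum", "Cecum", "Left colon"),
    gene_ids = c("GENE_A", "GENE_B", "GENE_C"),
    sample_ids = c("P1", "P2", "P3", "P4"))
}

# Random valid study for property-style tests.
random_study <- function(seed, n = 12L, m = 8L) {
  withr::with_seed(seed, {
    labels <- sample(ibd_classes(), n, replace = TRUE)
    # ensure at least one control and one of each IBD form
    labels[1:3] <- c("control", "UC", "CD")
    expression_study(
      expression = matrix(rnorm(m * n), nrow = m),
      labels = labels,
      age = sample(19:82, n, replace = TRUE),
      sex = sample(0:1, n, replace = TRUE),
      region = sample(ibd_regions(), n, replace = TRUE),
      gene_ids = sprintf("G%03d", seq_len(m)),
      sample_ids = sprintf("S%03d", seq_len(n)))
  })
}

# Strongly separated two-class data: samples x p features, n/2 per class,
# every feature shifted by `effect` sd units in class 1.
separable_data <- function(seed, n = 200L, p = 15L, effect = 5) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    X <- matrix(rnorm(n * p), nrow = n) + effect * y
    list(X = X, y = y)
  })
}

train_test <- function(dat, frac = 0.8) {
  n <- nrow(dat$X)
  tr <- seq_len(floor(frac * n))
  te <- setdiff(seq_len(n), tr)
  list(Xtr = dat$X[tr, , drop = FALSE], ytr = dat$y[tr],
       Xte = dat$X[te, , drop = FALSE], yte = dat$y[te])
}
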