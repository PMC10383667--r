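test_that("the registry holds exactly 23 distinct presets", {
  reg <- registry_list()
  expect_length(reg, 23L)
  expect_length(unique(names(reg)), 23L)
  expect_true(all(vapply(reg, inherits, TRUE, "model_spec")))
  expect_error(registry_list("fancy_net"), class = "ibdsig_registry_error")
  expect_error(model_spec("fancy_net"), class = "ibdsig_registry_error")
  expect_error(model_spec("fine_knn", hyper = list(bogus = 1)),
               class = "ibdsig_registry_error")
  expect_named(registry_desk(),
               c("bagged_trees", "linear_svm", "coarse_knn",
                 "simple_tree", "subspace_knn"))
})

test_that("confusion metrics follow their defining formulas", {
  m <- eval_metrics(tp = 5, fp = 2, tn = 8, fn = 5)
  expect_equal(m$sensitivity, 0.50)
  expect_equal(m$specificity, 0.80)
  expect_equal(m$accuracy, 0.65)

  # all-one predictions on 40% positives
  truth <- c(rep(1L, 4), rep(0L, 6))
  cc <- confusion_counts(truth, rep(1L, 10))
  m <- eval_metrics(cc[["tp"]], cc[["fp"]], cc[["tn"]], cc[["fn"]])
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$specificity, 0.0)
  expect_equal(m$accuracy, 0.40)

  # undefined ratios surface as NA, never 0
  m <- eval_metrics(tp = 3, fp = 0, tn = 0, fn = 1)
  expect_true(is.na(m$specificity))
  expect_equal(m$sensitivity, 0.75)
})

test_that("cross-validation bookkeeping is exact for a majority-vote baseline", {
  y <- c(rep(0L, 70), rep(1L, 30))
  X <- withr::with_seed(1, matrix(rnorm(100 * 3), nrow = 100))
  cv <- cross_validate(model_spec("majority_vote"), X, y, k_folds = 10,
                       seed = 9)
  expect_equal(cv$cv_accuracy, 0.70)
  expect_equal(unname(cv$counts),
               c(0L, 0L, 70L, 30L))  # tp fp tn fn: all predicted negative
  expect_equal(cv$fold_accuracies, rep(0.7, 10))

  cv2 <- cross_validate(model_spec("majority_vote"), X, y, k_folds = 10,
                        seed = 9)
  expect_identical(cv, cv2)
  expect_error(cross_validate(model_spec("majority_vote"), X, y,
                              k_folds = 200, seed = 1),
               class = "ibdsig_value_error")
  expect_error(cross_validate(model_spec("majority_vote"), X, rep(0L, 100),
                              k_folds = 10),
               class = "ibdsig_single_class_error")
})

test_that("stochastic learners are reproducible given the seed", {
  dat <- separable_data(2, n = 80, p = 10, effect = 1)
  tt <- train_test(dat)
  for (key in c("bagged_trees", "subspace_knn", "rusboosted_trees")) {
    r1 <- fit_and_evaluate(model_spec(key), NULL, tt$Xtr, tt$ytr,
                           tt$Xte, tt$yte, seed = 4)
    r2 <- fit_and_evaluate(model_spec(key), NULL, tt$Xtr, tt$ytr,
                           tt$Xte, tt$yte, seed = 4)
    expect_identical(r1$counts, r2$counts)
  }
})

test_that("every registry preset separates strongly shifted classes", {
  dat <- separable_data(3, n = 200, p = 15, effect = 5)
  tt <- train_test(dat)
  for (key in names(registry_list())) {
    res <- fit_and_evaluate(model_spec(key), NULL, tt$Xtr, tt$ytr,
                            tt$Xte, tt$yte, seed = 1)
    expect_gte(res$accuracy, 0.9)
  }
})

test_that("label permutation destroys test-set signal", {
  dat <- separable_data(5, n = 200, p = 10, effect = 3)
  tt <- train_test(dat)
  n_te <- length(tt$yte)
  p0 <- max(mean(tt$yte), 1 - mean(tt$yte))
  band <- qbinom(c(0.005, 0.995), n_te, p0) / n_te
  # model predictions are correlated through the shared training set, so
  # the binomial band is checked on the accuracy averaged over permutations
  for (key in c("linear_svm", "bagged_trees", "fine_knn")) {
    acc <- vapply(1:5, function(r) {
      y_perm <- withr::with_seed(600 + r, sample(tt$ytr))
      fit_and_evaluate(model_spec(key), NULL, tt$Xtr, y_perm,
                       tt$Xte, tt$yte, seed = 2)$accuracy
    }, 0)
    expect_gte(mean(acc), band[1] - 1e-9)
    expect_lte(mean(acc), band[2] + 1e-9)
  }
})

test_that("the network baseline conforms to the registry contract", {
  expect_error(ann_classifier(0), class = "ibdsig_value_error")

  dat <- separable_data(7, n = 100, p = 8, effect = 5)
  tt <- train_test(dat)
  m1 <- fit_model(ann_classifier(1), tt$Xtr, tt$ytr, seed = 1)
  pred <- predict_model(m1, tt$Xte)
  expect_true(all(pred %in% 0:1))

  res3 <- fit_and_evaluate(ann_classifier(3), NULL, tt$Xtr, tt$ytr,
                           tt$Xte, tt$yte, seed = 1)
  expect_gte(res3$accuracy, 0.95)
})

test_that("degenerate inputs are handled explicitly", {
  dat <- separable_data(8, n = 40, p = 4, effect = 2)
  expect_error(fit_model(model_spec("linear_svm"),
                         dat$X[, integer(0), drop = FALSE], dat$y),
               class = "ibdsig_dim_error")
  sub <- gene_subset(integer(0), m = 4)
  expect_error(fit_and_evaluate(model_spec("linear_svm"), sub, dat$X, dat$y,
                                dat$X, dat$y),
               class = "ibdsig_dim_error")
  # single-class test set: accuracy defined, specificity flagged NA
  res <- fit_and_evaluate(model_spec("fine_knn"), NULL, dat$X, dat$y,
                          dat$X[dat$y == 1, ], dat$y[dat$y == 1], seed = 1)
  expect_true(is.na(res$specificity))
  expect_false(is.na(res$accuracy))
})
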