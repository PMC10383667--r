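test_that("beta draws respect the uniform contract", {
  expect_error(sample_beta(1), class = "ibdsig_value_error")
  withr::with_seed(1, {
    expect_true(all(replicate(50, sample_beta(2)) == 1L))
    draws <- replicate(10000, sample_beta(566))
    expect_true(all(draws >= 1 & draws <= 565))
    # uniform mean (1 + 565) / 2 = 283, sd ~ 163.1
    se <- sqrt((565^2 - 1) / 12) / sqrt(10000)
    expect_lt(abs(mean(draws) - 283), 3 * se)
  })
})

test_that("subset reduction reproduces the worked reduction steps", {
  withr::with_seed(2, {
    s566 <- gene_subset(1:566, m = 1000)
    s536 <- reduce_subset(s566, 30)
    expect_equal(length(s536), 536L)
    expect_true(all(s536$indices %in% s566$indices))
    s411 <- reduce_subset(gene_subset(s536$indices, 1000), 125)
    expect_equal(length(s411), 411L)

    s10 <- gene_subset(seq(2, 20, 2), m = 30)
    s1 <- reduce_subset(s10, 9)
    expect_equal(length(s1), 1L)
    expect_true(s1$indices %in% s10$indices)
    expect_error(reduce_subset(s10, 10), class = "ibdsig_value_error")
    expect_error(reduce_subset(s10, 0), class = "ibdsig_value_error")
  })
})

test_that("chains nest strictly, respect the floor, and replay exactly", {
  gen <- generate_study(simulation_config(n_samples = 80, n_genes = 60,
                                          n_informative = 6, effect_size = 2,
                                          seed = 41))
  enc <- encode_labels(gen$study, label_scheme("control_vs_ibd"))
  sp <- split_train_test(gen$study, enc$kept, seed = 2)
  ytr <- enc$y[match(sp$train, enc$kept)]
  Xtr <- t(gen$study$expression[, sp$train])
  filt <- top_q_filter(
    correlation_screen(gen$study$expression[, sp$train], ytr), 50)

  reg <- registry_list(c("simple_tree", "linear_svm"))
  ch <- run_chain(filt, Xtr, ytr, registry = reg, cv_folds = 5,
                  min_size = 5, seed = 7)
  expect_s3_class(ch, "mc_chain")
  expect_equal(ch$records$n_genes[1], length(filt))
  sizes <- ch$records$n_genes
  expect_true(all(diff(sizes) < 0))
  expect_gte(min(sizes), 5L)
  betas <- ch$records$beta
  expect_true(all(betas[-length(betas)] >= 1 &
                  betas[-length(betas)] <= sizes[-length(sizes)] - 1))
  for (i in seq_len(length(ch$subsets) - 1)) {
    expect_true(all(ch$subsets[[i + 1]]$indices %in% ch$subsets[[i]]$indices))
    expect_lt(length(ch$subsets[[i + 1]]), length(ch$subsets[[i]]))
  }
  expect_equal(vapply(ch$best, function(e) length(e$subset), 0L), sizes)

  ch2 <- run_chain(filt, Xtr, ytr, registry = reg, cv_folds = 5,
                   min_size = 5, seed = 7)
  expect_identical(ch, ch2)

  # immediate stop: the floor equals the filtered size
  ch0 <- run_chain(filt, Xtr, ytr, registry = reg, cv_folds = 5,
                   min_size = length(filt), seed = 7)
  expect_equal(nrow(ch0$records), 1L)
})

test_that("the search produces a ranked, deterministic leaderboard", {
  gen <- generate_study(simulation_config(n_samples = 100, n_genes = 80,
                                          n_informative = 8, effect_size = 2,
                                          seed = 51))
  reg <- registry_list(c("simple_tree", "linear_svm"))
  res <- run_search(gen$study, label_scheme("control_vs_ibd"), q = 25,
                    p_chains = 3, registry = reg, cv_folds = 5,
                    min_size = 5, seed = 13)
  lb <- res$leaderboard
  expect_lte(nrow(lb), 10L)
  expect_true(all(diff(lb$cv_accuracy) <= 0))
  expect_true(all(lb$algorithm %in% names(reg)))
  expect_true(all(lb$accuracy >= 0 & lb$accuracy <= 1))

  res2 <- run_search(gen$study, label_scheme("control_vs_ibd"), q = 25,
                     p_chains = 3, registry = reg, cv_folds = 5,
                     min_size = 5, seed = 13)
  expect_identical(res$leaderboard, res2$leaderboard)

  # degenerate search: one chain stopped at the filter is a one-row board
  res1 <- run_search(gen$study, label_scheme("control_vs_ibd"), q = 25,
                     p_chains = 1, registry = reg, cv_folds = 5,
                     min_size = 1000, seed = 13)
  expect_equal(nrow(res1$leaderboard), 1L)
  expect_equal(res1$leaderboard$n_genes, length(res1$filtered))
})

test_that("the depth sweep picks the most accurate, shallowest network", {
  dat <- separable_data(9, n = 100, p = 8, effect = 5)
  tt <- train_test(dat)
  sw1 <- ann_layer_sweep(tt$Xtr, tt$ytr, tt$Xte, tt$yte, layer_values = 3,
                         seed = 1)
  expect_equal(sw1$best_layers, 3L)
  expect_s3_class(sw1$best, "eval_result")

  sw <- ann_layer_sweep(tt$Xtr, tt$ytr, tt$Xte, tt$yte,
                        layer_values = c(1, 2, 4), seed = 1)
  expect_gte(sw$best$accuracy, 0.95)
  # separable data ties all depths at 1.0: the tie goes to the shallowest
  if (sum(sw$table$accuracy == max(sw$table$accuracy)) > 1) {
    expect_equal(sw$best_layers,
                 min(sw$table$layers[sw$table$accuracy ==
                                     max(sw$table$accuracy)]))
  }
  expect_error(ann_layer_sweep(tt$Xtr, tt$ytr, tt$Xte, tt$yte,
                               layer_values = integer(0)),
               class = "ibdsig_value_error")
})

test_that("final selection takes the larger accuracy, non-network on ties", {
  ml <- list(accuracy = 0.842)
  ann <- list(best = list(accuracy = 0.8035))
  expect_equal(select_best(ml, ann)$source, "ml")
  expect_equal(select_best(ml, ann)$accuracy, 0.842)

  expect_equal(select_best(list(accuracy = 0.8),
                           list(best = list(accuracy = 0.8)))$source, "ml")
  expect_equal(select_best(list(accuracy = 0.7),
                           list(best = list(accuracy = 0.9)))$source, "ann")
})
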