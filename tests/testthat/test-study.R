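test_that("study construction enforces the data-model invariants", {
  s <- tiny_study()
  expect_s3_class(s, "expression_study")
  expect_equal(n_genes(s), 3L)
  expect_equal(n_samples(s), 4L)

  bad_expr <- matrix(c(1, NA, 3, 4), nrow = 1)
  expect_error(
    expression_study(rbind(bad_expr, bad_expr + 1),
                     labels = c("UC", "CD", "UC", "control"),
                     age = rep(40, 4), sex = rep(0, 4),
                     region = rep("Rectum", 4),
                     gene_ids = c("a", "b"), sample_ids = letters[1:4]),
    class = "ibdsig_value_error")
  expect_error(
    expression_study(matrix(1:8, 2), labels = c("UC", "XX", "CD", "control"),
                     age = rep(40, 4), sex = rep(0, 4),
                     region = rep("Rectum", 4),
                     gene_ids = c("a", "b"), sample_ids = letters[1:4]),
    class = "ibdsig_label_error")
  expect_error(
    expression_study(matrix(1:8, 2), labels = rep("UC", 4),
                     age = rep(40, 4), sex = rep(0, 4),
                     region = c("Rectum", "Nowhere", "Ileum", "Cecum"),
                     gene_ids = c("a", "b"), sample_ids = letters[1:4]),
    class = "ibdsig_region_error")
  expect_error(
    expression_study(matrix(1:8, 2), labels = rep("UC", 4),
                     age = rep(40, 4), sex = rep(0, 4),
                     region = rep("Rectum", 4),
                     gene_ids = c("a", "a"), sample_ids = letters[1:4]),
    class = "ibdsig_duplicate_id_error")
})

test_that("label encoding implements both task mappings", {
  s <- tiny_study()  # labels UC, control, CD, control
  enc <- encode_labels(s, label_scheme("control_vs_ibd"))
  expect_equal(enc$y, c(1L, 0L, 1L, 0L))
  expect_equal(enc$kept, 1:4)

  enc2 <- encode_labels(s, label_scheme("uc_vs_cd"))
  expect_equal(enc2$kept, c(1L, 3L))
  expect_equal(enc2$y, c(0L, 1L))

  # re-encoding kept samples yields the same vector (idempotent in effect)
  s_sub <- expression_study(s$expression[, enc2$kept], s$labels[enc2$kept],
                            s$age[enc2$kept], s$sex[enc2$kept],
                            s$region[enc2$kept],
                            gene_ids = s$gene_ids,
                            sample_ids = s$sample_ids[enc2$kept])
  expect_equal(encode_labels(s_sub, label_scheme("uc_vs_cd"))$y, enc2$y)

  all_ctrl <- expression_study(matrix(rnorm(8), 2), rep("control", 4),
                               rep(40, 4), rep(0, 4), rep("Rectum", 4),
                               gene_ids = c("a", "b"),
                               sample_ids = letters[1:4])
  expect_error(encode_labels(all_ctrl, label_scheme("control_vs_ibd")),
               class = "ibdsig_single_class_error")
})

test_that("train/test split partitions with the contracted sizes", {
  s <- random_study(1, n = 10)
  enc <- encode_labels(s, label_scheme("control_vs_ibd"))
  sp <- split_train_test(s, enc$kept, fraction = 0.8, seed = 5)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), enc$kept)

  sp2 <- split_train_test(s, enc$kept, fraction = 0.8, seed = 5)
  expect_identical(sp, sp2)

  # cohort-scale arithmetic: 2490 samples at 80% -> 1992 / 498
  big <- withr::with_seed(9, expression_study(
    matrix(rnorm(2490), nrow = 1),
    labels = sample(ibd_classes(), 2490, replace = TRUE),
    age = sample(19:82, 2490, replace = TRUE),
    sex = sample(0:1, 2490, replace = TRUE),
    region = sample(ibd_regions(), 2490, replace = TRUE),
    gene_ids = "g1", sample_ids = sprintf("S%04d", 1:2490)))
  spb <- split_train_test(big, seq_len(2490), seed = 1)
  expect_length(spb$train, 1992L)
  expect_length(spb$test, 498L)

  # partition property across seeds, stratified and not
  for (seed in 1:10) {
    for (strat in c(TRUE, FALSE)) {
      sp <- split_train_test(big, seq_len(2490), seed = seed,
                             stratify = strat)
      expect_length(intersect(sp$train, sp$test), 0L)
      expect_setequal(c(sp$train, sp$test), seq_len(2490))
    }
  }
  # stratified splits keep every class in both halves
  expect_setequal(unique(big$labels[spb$train]), ibd_classes())
  expect_setequal(unique(big$labels[spb$test]), ibd_classes())

  expect_error(split_train_test(s, enc$kept, fraction = 1.2),
               class = "ibdsig_value_error")
  expect_error(split_train_test(s, kept = 1L), class = "ibdsig_dim_error")
})

test_that("study TSV round-trips bit-identically", {
  path <- withr::local_tempfile(fileext = ".tsv")
  s <- tiny_study()
  write_study(s, path)
  expect_identical(read_study(path), s)

  # property: round-trip identity over randomly generated studies
  for (seed in 1:5) {
    s <- random_study(seed)
    write_study(s, path)
    expect_identical(read_study(path), s)
  }
})

test_that("study TSV parser raises named errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_study(tiny_study(), path)
  lines <- readLines(path)

  bad <- lines
  bad[3] <- sub("52", "abc", bad[3])  # age row
  writeLines(bad, path)
  err <- expect_error(read_study(path), class = "ibdsig_parse_error")
  expect_match(conditionMessage(err), "age")

  bad <- lines
  bad[8] <- sub("GENE_C", "GENE_A", bad[8])
  writeLines(bad, path)
  expect_error(read_study(path), class = "ibdsig_duplicate_id_error")

  bad <- c(lines, "ragged\t1")
  writeLines(bad, path)
  expect_error(read_study(path), class = "ibdsig_parse_error")

  expect_error(read_study(file.path(tempdir(), "nope.tsv")),
               class = "ibdsig_io_error")
})
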