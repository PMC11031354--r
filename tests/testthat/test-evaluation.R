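test_that("roc_auc matches the pairwise Mann-Whitney oracle", {
  # perfect separation and the all-tied case
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.3, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  # single-class gold is undefined, not an exception
  expect_true(is.na(roc_auc(c(0.1, 0.2), c(1, 1))))

  set.seed(41)
  for (trial in 1:100) {
    n <- sample(5:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    gold <- rbinom(n, 1, 0.4)
    if (sum(gold) %in% c(0, n)) next
    expect_equal(roc_auc(scores, gold), auc_pair_oracle(scores, gold),
                 tolerance = 1e-9)
    # complement symmetry
    expect_equal(roc_auc(1 - scores, gold), 1 - roc_auc(scores, gold),
                 tolerance = 1e-12)
  }
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  for (trial in 1:10) {
    scores <- runif(40)
    gold <- rbinom(40, 1, 0.5)
    if (sum(gold) %in% c(0, 40)) next
    ref <- suppressMessages(as.numeric(pROC::auc(gold, scores,
                                                 direction = "<")))
    expect_equal(roc_auc(scores, gold), ref, tolerance = 1e-9)
  }
})

test_that("auprc matches the exhaustive threshold-sweep oracle", {
  # perfect ranking
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # all scores tied: area equals prevalence
  expect_equal(auprc(rep(0.5, 4), c(1, 0, 1, 0)), 0.5)
  expect_true(is.na(auprc(c(0.4, 0.6), c(0, 0))))

  set.seed(47)
  for (trial in 1:100) {
    n <- sample(5:30, 1)
    scores <- sample(seq(0, 1, by = 0.2), n, replace = TRUE)
    gold <- rbinom(n, 1, 0.3)
    if (sum(gold) %in% c(0, n)) next
    expect_equal(auprc(scores, gold), auprc_sweep_oracle(scores, gold),
                 tolerance = 1e-9)
  }
})

test_that("per-type evaluation is independent across columns", {
  # a cell gold-annotated to a child A and its parent A' counts in both
  # columns; confident support for A' only ranks well there and poorly for A
  g <- cell_type_graph(data.frame(child = "A", parent = "Aprime",
                                  relation = "parent"))
  raw <- label_matrix(c("A", "A", "Aprime", "Aprime"),
                      paste0("c", 1:4), c("A", "Aprime"))
  gold <- propagate_label_matrix(raw, g)
  scores <- rbind(c(0.1, 0.9), c(0.2, 0.8), c(0.7, 0.9), c(0.6, 0.8))
  colnames(scores) <- c("A", "Aprime")
  # all four cells are positive for Aprime -> undefined there
  expect_true(is.na(roc_auc(scores[, "Aprime"], gold[, "Aprime"])))
  # for A, the two true A cells are outscored by the two Aprime-only cells
  expect_equal(roc_auc(scores[, "A"], gold[, "A"]), 0)
})

test_that("evaluate_fold equals recomputation from extracted columns", {
  fx <- tiny_corpus_store()
  split <- split_by_dataset(unique(fx$store$manifest$dataset_id), 0.25, seed = 2)
  gold <- propagate_label_matrix(fx$labels, fx$graph)
  cfg <- model_config(80, ncol(gold), hidden_widths = c(16, 8),
                      output_activation = "sigmoid", epochs = 2, seed = 5)
  model <- fit_celltype_nn(fx$store, gold, split, cfg)

  man <- fx$store$manifest
  test_chunks <- which(man$dataset_id %in% split$test_datasets)
  fm <- evaluate_fold(model, fx$store, test_chunks, gold)

  # column-extraction oracle
  scores <- predict(model, fx$store, chunks = test_chunks)
  row_end <- cumsum(man$n_cells)
  test_rows <- unlist(lapply(test_chunks,
                             function(i) (row_end[i] - man$n_cells[i] + 1):row_end[i]))
  for (k in seq_len(nrow(fm))) {
    ty <- fm$type_id[k]
    y <- unclass(gold)[test_rows, ty]
    expect_equal(fm$auc[k], roc_auc(scores[, ty], y))
    expect_equal(fm$auprc[k], auprc(scores[, ty], y))
    expect_equal(fm$n_pos[k], sum(y == 1))
  }

  # a type absent from the training gold is not evaluated
  fake_types <- setdiff(fm$type_id, fm$type_id[1])
  fm2 <- evaluate_fold(model, fx$store, test_chunks, gold,
                       train_types = fake_types)
  expect_false(fm$type_id[1] %in% fm2$type_id)
})

test_that("summaries aggregate and filter as specified", {
  mk_report <- function(metrics) {
    ontoAnnot:::new_evaluation_report(metrics, folds = list(), mode = "raw",
                                      split_level = "dataset", n_folds = 10,
                                      test_fraction = 0.2,
                                      min_evaluations = 5, seed = 1)
  }
  # single type, single fold
  r1 <- mk_report(data.frame(type_id = "T cell", auc = 0.8, auprc = 0.7,
                             n_pos = 5, n_neg = 5, fold = 1))
  expect_equal(summary(r1, min_evaluations = 1)$median_auc, 0.8)

  # counts {6, 3} with threshold 5: only the first type enters the median
  m <- rbind(
    data.frame(type_id = "a", auc = seq(0.9, 0.95, length.out = 6),
               auprc = 0.5, n_pos = 5, n_neg = 5, fold = 1:6),
    data.frame(type_id = "b", auc = c(0.1, 0.2, 0.3), auprc = 0.5,
               n_pos = 5, n_neg = 5, fold = 1:3))
  s <- summary(mk_report(m))
  expect_equal(s$per_type$eligible, c(TRUE, FALSE))
  expect_equal(s$median_auc, mean(seq(0.9, 0.95, length.out = 6)))

  # random report: median equals the sort-and-middle oracle
  set.seed(53)
  types <- paste0("t", 1:9)
  m2 <- do.call(rbind, lapply(types, function(ty) {
    data.frame(type_id = ty, auc = runif(6), auprc = runif(6),
               n_pos = 3, n_neg = 7, fold = 1:6)
  }))
  s2 <- summary(mk_report(m2))
  means <- sort(tapply(m2$auc, m2$type_id, mean))
  expect_equal(s2$median_auc, means[[5]])

  # raising min_evaluations never adds types
  elig5 <- summary(mk_report(m), min_evaluations = 5)$per_type$eligible
  elig6 <- summary(mk_report(m), min_evaluations = 6)$per_type$eligible
  expect_true(all(which(elig6) %in% which(elig5)))
})

test_that("cross-validation drivers are seeded and well-formed", {
  fx <- tiny_corpus_store()
  cfg <- model_config(80, ncol(fx$labels), hidden_widths = c(16, 8), epochs = 2)

  r1 <- cross_dataset_cv(fx$store, fx$labels, fx$graph, mode = "raw",
                         n_folds = 1, test_fraction = 0.25, config = cfg,
                         seed = 7)
  expect_equal(unique(r1$metrics$fold), 1)
  r1b <- cross_dataset_cv(fx$store, fx$labels, fx$graph, mode = "raw",
                          n_folds = 1, test_fraction = 0.25, config = cfg,
                          seed = 7)
  expect_identical(r1$metrics, r1b$metrics)

  # corrected mode requires the graph
  expect_error(cross_dataset_cv(fx$store, fx$labels, mode = "corrected",
                                n_folds = 1, config = cfg, seed = 1),
               "cell_type_graph")

  # cell-level CV runs even on a single dataset, where dataset-level cannot
  one <- tiny_corpus_store("oneds", simulation_config(
    n_datasets = 1, cells_per_dataset = 300, n_genes = 50,
    n_leaf_types = 4, n_parent_types = 2, n_synonym_pairs = 0,
    markers_per_type = 5, batch_sd = 0, granularity_fraction = 0,
    n_synonym_datasets = 0, seed = 8))
  cfg1 <- model_config(50, ncol(one$labels), hidden_widths = c(16, 8), epochs = 2)
  rc <- cross_cell_cv(one$store, one$labels, mode = "raw", n_folds = 2,
                      test_fraction = 0.25, config = cfg1,
                      validation_fraction = 0.5, seed = 3)
  expect_equal(sort(unique(rc$metrics$fold)), 1:2)
  expect_error(cross_dataset_cv(one$store, one$labels, mode = "raw",
                                n_folds = 1, config = cfg1, seed = 3),
               ">= 2 datasets")

  # report writer emits the three artifacts
  dir <- withr::local_tempdir()
  write_report(r1, dir)
  expect_true(all(file.exists(file.path(dir, c("per_type_metrics.tsv",
                                               "summary.tsv",
                                               "config.yaml")))))
})
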