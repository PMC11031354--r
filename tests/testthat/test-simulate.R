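test_that("simulated ontologies have the configured shape", {
  cfg <- simulation_config(n_leaf_types = 4, n_parent_types = 2,
                           n_synonym_pairs = 1, n_genes = 100,
                           markers_per_type = 5)
  onto <- simulate_ontology(cfg)
  g <- onto$graph
  expect_length(g$nodes, 4 + 2 + 1)
  expect_equal(sum(g$edges$kind == "parent"), 4)
  expect_equal(sum(g$edges$kind == "synonym"), 2)  # both directions

  # minimal two-node chain
  cfg1 <- simulation_config(n_leaf_types = 1, n_parent_types = 1,
                            n_synonym_pairs = 0, n_genes = 50,
                            markers_per_type = 5)
  g1 <- simulate_ontology(cfg1)$graph
  expect_length(g1$nodes, 2)
  expect_equal(nrow(g1$edges), 1)

  # each leaf's closure is exactly {leaf, its parent} plus synonyms
  for (leaf in names(onto$leaf_parent)) {
    cl <- as.character(propagate_labels(leaf, g))
    expected <- c(leaf, onto$leaf_parent[[leaf]])
    if (leaf %in% names(onto$synonyms)) {
      expected <- c(expected, onto$synonyms[[leaf]])
    }
    expect_setequal(cl, expected)
  }

  expect_error(simulation_config(n_leaf_types = 2, n_synonym_pairs = 3,
                                 n_parent_types = 1),
               "synonym pairs")
  expect_error(simulation_config(n_leaf_types = 2, n_parent_types = 3),
               "n_leaf_types")
  expect_error(simulation_config(n_genes = 20),
               "marker assignment")
})

test_that("expression model recovers its configured means", {
  # null model: no markers, no batch effects
  cfg0 <- simulation_config(n_datasets = 2, cells_per_dataset = 400,
                            n_genes = 60, n_leaf_types = 3,
                            n_parent_types = 1, n_synonym_pairs = 0,
                            markers_per_type = 4, marker_effect = 0,
                            batch_sd = 0, base_mean = 2, dispersion = 2,
                            seed = 101)
  corp0 <- simulate_expression(cfg0)
  counts <- do.call(rbind, lapply(corp0$datasets, function(d) d$matrix))
  gm <- colMeans(counts)
  # NB variance = mu + mu^2/size; the grand mean must sit within 3 standard
  # errors of base_mean and no single gene may stray far (4.5 SE allows for
  # the 60 simultaneous per-gene comparisons)
  se <- sqrt((2 + 4 / 2) / nrow(counts))
  expect_lt(abs(mean(gm) - 2), 3 * se / sqrt(length(gm)))
  expect_true(all(abs(gm - 2) < 4.5 * se))

  # two leaves under one parent both express the parent's markers
  cfg <- simulation_config(n_datasets = 2, cells_per_dataset = 500,
                           n_genes = 80, n_leaf_types = 2,
                           n_parent_types = 1, n_synonym_pairs = 0,
                           markers_per_type = 6, marker_effect = 4,
                           batch_sd = 0, base_mean = 1, seed = 7)
  corp <- simulate_expression(cfg)
  pm <- corp$markers[["parent_type_1"]]
  for (leaf in c("leaf_type_01", "leaf_type_02")) {
    rows <- do.call(rbind, lapply(corp$datasets, function(d) {
      d$matrix[d$true_label == leaf, , drop = FALSE]
    }))
    uplift <- mean(rows[, pm]) / mean(rows[, -pm])
    # configured uplift is (1 + marker_effect) = 5x over non-marker genes
    # of which a fraction are the leaf's own markers; demand a clear signal
    expect_gt(uplift, 3)
  }

  # same seed, bitwise-identical corpus
  corp2 <- simulate_expression(cfg)
  expect_identical(corp$datasets, corp2$datasets)
})

test_that("annotation distortion rewrites labels per dataset role", {
  shape <- list(n_leaf_types = 6L, n_parent_types = 2L, n_synonym_pairs = 1L,
                markers_per_type = 5L)
  # identity when nothing is distorted
  cfg_id <- do.call(simulation_config, c(shape, list(
    n_datasets = 3, cells_per_dataset = 50, n_genes = 100,
    granularity_fraction = 0, n_synonym_datasets = 0, seed = 5)))
  corp_id <- simulate_corpus(cfg_id)
  for (d in corp_id$datasets) {
    expect_identical(d$observed_label, d$true_label)
  }

  # full granularity distortion: no leaf label survives
  cfg_all <- do.call(simulation_config, c(shape, list(
    n_datasets = 3, cells_per_dataset = 50, n_genes = 100,
    granularity_fraction = 1, n_synonym_datasets = 0, seed = 5)))
  corp_all <- simulate_corpus(cfg_all)
  observed <- unlist(lapply(corp_all$datasets, function(d) d$observed_label))
  expect_false(any(grepl("^leaf_", observed)))
  expect_true(all(grepl("^parent_", observed)))

  # mixed config: distortion stays on-graph and the closure of the observed
  # label always contains the true leaf's parent
  cfg_mix <- do.call(simulation_config, c(shape, list(
    n_datasets = 6, cells_per_dataset = 50, n_genes = 100,
    granularity_fraction = 0.5, n_synonym_datasets = 2, seed = 5)))
  corp_mix <- simulate_corpus(cfg_mix)
  g <- corp_mix$ontology$graph
  closures <- ontoAnnot:::label_closures(
    unique(unlist(lapply(corp_mix$datasets, function(d) d$observed_label))), g)
  for (d in corp_mix$datasets) {
    expect_true(all(d$observed_label %in% g$nodes))
    parents <- corp_mix$ontology$leaf_parent[d$true_label]
    cl_has_parent <- vapply(seq_along(parents), function(i) {
      parents[[i]] %in% closures[[d$observed_label[i]]]
    }, logical(1))
    expect_true(all(cl_has_parent))
  }
  # roles recorded and disjoint
  expect_length(intersect(corp_mix$distortion$granularity_datasets,
                          corp_mix$distortion$synonym_datasets), 0)

  # synonym datasets use the alternate label for synonymous leaves
  syn_ds <- corp_mix$distortion$synonym_datasets
  if (length(syn_ds) > 0) {
    d <- corp_mix$datasets[[syn_ds[1]]]
    syn_map <- corp_mix$ontology$synonyms
    affected <- d$true_label %in% names(syn_map)
    expect_true(any(affected))
    expect_identical(d$observed_label[affected],
                     unname(syn_map[d$true_label[affected]]))
    expect_identical(d$observed_label[!affected], d$true_label[!affected])
  }
})

test_that("corpus export writes loadable datasets plus edges and truth", {
  fx <- tiny_corpus_store()
  dir <- withr::local_tempdir()
  write_corpus(fx$corpus, dir)

  expect_true(file.exists(file.path(dir, "edges.tsv")))
  g <- load_edge_table(file.path(dir, "edges.tsv"), verbose = FALSE)
  expect_setequal(g$nodes, fx$graph$nodes)

  ds1 <- names(fx$corpus$datasets)[1]
  back <- load_expression(file.path(dir, ds1))
  expect_identical(unname(as.matrix(back$matrix)),
                   unname(t(fx$corpus$datasets[[ds1]]$matrix)))

  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), corpus_cell_count(fx$corpus))
  expect_true(all(truth$distortion %in% c("granularity", "synonym", "none")))
  expect_true(all(c("granularity", "synonym") %in% truth$distortion))
})
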