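# Shared fixtures and independent oracles, built in code.

# Small curated relationship table mirroring the ciliated / endothelial
# examples the correction targets.
example_edge_df <- function() {
  data.frame(
    child = c("ciliated columnar cell of tracheobronchial tree",
              "ciliated epithelial cell",
              "lung ciliated cell",
              "ciliated epithelial cell",
              "blood vessel endothelial cell"),
    parent = c("ciliated cell", "ciliated cell", "ciliated cell",
               "epithelial cell", "vein endothelial cell"),
    relation = c("parent", "parent", "parent", "parent", "synonym"),
    stringsAsFactors = FALSE
  )
}

# Independent closure oracle: repeated edge relaxation until no set grows.
# Works directly on the (from, to) edge list, one relaxation sweep at a time.
closure_oracle <- function(labels, edge_from, edge_to) {
  out <- unique(labels)
  repeat {
    add <- edge_to[edge_from %in% out]
    new <- union(out, add)
    if (length(new) == length(out)) return(sort(out))
    out <- new
  }
}

# Random graph in curated-table form: n nodes, m edge rows, mixed kinds.
random_edge_df <- function(n_nodes, n_edges) {
  nodes <- sprintf("ct%02d", seq_len(n_nodes))
  from <- sample(nodes, n_edges, replace = TRUE)
  to <- sample(nodes, n_edges, replace = TRUE)
  keep <- from != to
  data.frame(child = from[keep], parent = to[keep],
             relation = sample(c("parent", "synonym"), sum(keep),
                               replace = TRUE),
             stringsAsFactors = FALSE)
}

# Directed edge list implied by a curated table (synonyms both ways),
# for feeding closure_oracle.
directed_edges <- function(df) {
  syn <- df$relation == "synonym"
  list(from = c(df$child, df$parent[syn]), to = c(df$parent, df$child[syn]))
}

# O(n^2) pairwise Mann-Whitney oracle for the AUC.
auc_pair_oracle <- function(scores, gold) {
  pos <- scores[gold == 1]
  neg <- scores[gold == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive threshold-sweep oracle for average precision: walk the unique
# score values in descending order, accumulating precision at each recall
# increment (ties grouped at one threshold).
auprc_sweep_oracle <- function(scores, gold) {
  n_pos <- sum(gold == 1)
  if (n_pos == 0 || n_pos == length(gold)) return(NA_real_)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  for (th in thresholds) {
    called <- scores >= th
    tp <- sum(gold == 1 & called)
    precision <- tp / sum(called)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Small simulated corpus + chunk store for pipeline tests; cached per
# (label) so repeated calls in one run reuse the store.
.fixture_cache <- new.env(parent = emptyenv())

tiny_corpus_store <- function(key = "default", config = NULL) {
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  config <- config %||% simulation_config(
    n_datasets = 4, cells_per_dataset = 300, n_genes = 80,
    n_leaf_types = 6, n_parent_types = 2, n_synonym_pairs = 1,
    markers_per_type = 5, seed = 42)
  corpus <- simulate_corpus(config)
  dir <- file.path(tempdir(), paste0("store_", key))
  unlink(dir, recursive = TRUE)
  store <- corpus_to_store(corpus, dir)
  labels <- store_label_matrix(store,
                               type_ids = sort(corpus$ontology$graph$nodes))
  out <- list(corpus = corpus, store = store, labels = labels,
              graph = corpus$ontology$graph)
  .fixture_cache[[key]] <- out
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
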