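# Synthetic multi-dataset scRNA-seq corpora.
#
# The generator emulates the two annotation error modes that ontology
# correction targets — hierarchical error (datasets annotating at parent
# rather than leaf granularity) and synonym error (the same type recorded
# under two label strings) — on top of a minimal expression model with real
# type signal and dataset batch effects: negative-binomial counts whose
# per-gene means carry a marker-gene uplift for the cell's type lineage and
# a log-normal per-dataset x gene offset. Markers are assigned
# hierarchically (a parent's markers are shared by all its leaves), so
# parent-level annotations are learnable and the correction effect can be
# demonstrated.

#' Simulation configuration
#'
#' Defaults describe the package's reference corpus: 8 datasets of 1,500
#' cells over 300 genes, with 12 leaf types under 4 parents and 2 synonym
#' pairs; half the datasets annotate at parent granularity and 2 use the
#' alternate synonym labels.
#'
#' @param n_datasets Number of datasets (batches); default 8.
#' @param cells_per_dataset Cells per dataset; default 1500.
#' @param n_genes Gene vocabulary size; default 300.
#' @param n_leaf_types,n_parent_types Leaf and parent type counts (each leaf
#'   gets exactly one parent, round-robin); defaults 12 and 4.
#' @param n_synonym_pairs Leaves that also carry an alternate (synonymous)
#'   label string; default 2.
#' @param markers_per_type Marker genes per type (disjoint across types);
#'   default 8.
#' @param marker_effect Mean uplift factor for a type's markers: marker
#'   means are `(1 + marker_effect)` times the baseline; default 4.
#' @param base_mean Baseline negative-binomial mean per gene; default 1.
#' @param dispersion Negative-binomial size parameter; default 2.
#' @param granularity_fraction Fraction of datasets annotating at parent
#'   level; default 0.5.
#' @param n_synonym_datasets Leaf-level datasets that use the alternate
#'   synonym labels; default 2.
#' @param batch_sd SD of the per-dataset x gene log-scale offset; default
#'   0.4. Zero switches batch effects off.
#' @param seed Integer seed; every stage of the generator is deterministic
#'   given it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_datasets = 8L, cells_per_dataset = 1500L,
                              n_genes = 300L, n_leaf_types = 12L,
                              n_parent_types = 4L, n_synonym_pairs = 2L,
                              markers_per_type = 8L, marker_effect = 4,
                              base_mean = 1, dispersion = 2,
                              granularity_fraction = 0.5,
                              n_synonym_datasets = 2L, batch_sd = 0.4,
                              seed = 1L) {
  if (n_leaf_types < n_parent_types || n_parent_types < 1) {
    stop_fmt("need n_leaf_types >= n_parent_types >= 1")
  }
  if (n_synonym_pairs > n_leaf_types) {
    stop_fmt("more synonym pairs (%d) than leaf types (%d)",
             n_synonym_pairs, n_leaf_types)
  }
  if ((n_leaf_types + n_parent_types) * markers_per_type > n_genes) {
    stop_fmt("marker assignment needs %d genes but only %d available",
             (n_leaf_types + n_parent_types) * markers_per_type, n_genes)
  }
  if (granularity_fraction < 0 || granularity_fraction > 1) {
    stop_fmt("granularity_fraction must be in [0, 1]")
  }
  stopifnot(n_datasets >= 1, cells_per_dataset >= 1, base_mean > 0,
            dispersion > 0, marker_effect >= 0, batch_sd >= 0)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a cell-type ontology
#'
#' Builds the generating [cell_type_graph()]: each leaf type gets exactly
#' one parent (leaves distributed round-robin over parents), and the first
#' `n_synonym_pairs` leaves get an alternate label connected by a synonym
#' relation.
#'
#' @param config A [simulation_config()].
#' @return A list with `graph` (the `cell_type_graph`), `leaf_parent`
#'   (named character: leaf -> parent), `synonyms` (named character:
#'   leaf -> alternate label) and `edge_table` (the curated-table form,
#'   columns `child`, `parent`, `relation`).
#' @export
simulate_ontology <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  leaves <- sprintf("leaf_type_%02d", seq_len(config$n_leaf_types))
  parents <- sprintf("parent_type_%d", seq_len(config$n_parent_types))
  leaf_parent <- stats::setNames(
    parents[((seq_along(leaves) - 1L) %% config$n_parent_types) + 1L], leaves)

  syn_leaves <- leaves[seq_len(config$n_synonym_pairs)]
  synonyms <- stats::setNames(paste0(syn_leaves, "_syn"), syn_leaves)

  edge_table <- rbind(
    data.frame(child = leaves, parent = unname(leaf_parent),
               relation = "parent"),
    if (length(syn_leaves) > 0) {
      data.frame(child = syn_leaves, parent = unname(synonyms),
                 relation = "synonym")
    }
  )
  list(graph = cell_type_graph(edge_table),
       leaf_parent = leaf_parent,
       synonyms = synonyms,
       edge_table = edge_table)
}

#' Simulate expression for a multi-dataset corpus
#'
#' Draws each cell's true leaf type uniformly, then counts
#' `NB(mu, size = dispersion)` with
#' `mu = base_mean * exp(offset[dataset, gene]) * (1 + marker_effect * m)`,
#' where `m` indicates the gene is a marker of the cell's leaf or of its
#' parent, and offsets are `Normal(0, batch_sd)` per dataset x gene.
#'
#' @param config A [simulation_config()].
#' @param ontology Result of [simulate_ontology()]; simulated afresh from
#'   `config` when omitted.
#' @return A `simulated_corpus`: list with `datasets` (per dataset: `matrix`
#'   cells x genes, `cell_ids`, `true_label`, `observed_label`, initially
#'   equal to `true_label`), `gene_ids`, `markers` (per type), `ontology`
#'   and `config`.
#' @export
simulate_expression <- function(config, ontology = simulate_ontology(config)) {
  stopifnot(inherits(config, "simulation_config"))
  gene_ids <- sprintf("gene_%04d", seq_len(config$n_genes))
  leaves <- names(ontology$leaf_parent)
  parents <- unique(unname(ontology$leaf_parent))
  types_with_markers <- c(parents, leaves)

  with_seed(derive_seed(config$seed, 11L), {
    pool <- sample(config$n_genes)
    markers <- stats::setNames(vector("list", length(types_with_markers)),
                               types_with_markers)
    k <- 0L
    for (ty in types_with_markers) {
      markers[[ty]] <- sort(pool[(k + 1L):(k + config$markers_per_type)])
      k <- k + config$markers_per_type
    }

    ds_ids <- sprintf("dataset_%02d", seq_len(config$n_datasets))
    offsets <- matrix(stats::rnorm(config$n_datasets * config$n_genes,
                                   0, config$batch_sd),
                      config$n_datasets, config$n_genes,
                      dimnames = list(ds_ids, gene_ids))

    # per-leaf gene-mean multiplier: leaf markers + inherited parent markers
    mult <- stats::setNames(lapply(leaves, function(l) {
      m <- rep(1, config$n_genes)
      idx <- c(markers[[l]], markers[[ontology$leaf_parent[[l]]]])
      m[idx] <- 1 + config$marker_effect
      m
    }), leaves)

    datasets <- stats::setNames(vector("list", config$n_datasets), ds_ids)
    for (d in seq_len(config$n_datasets)) {
      n <- config$cells_per_dataset
      true_leaf <- sample(leaves, n, replace = TRUE)
      base_d <- config$base_mean * exp(offsets[d, ])
      mu <- t(vapply(true_leaf, function(l) base_d * mult[[l]],
                     numeric(config$n_genes)))
      counts <- matrix(stats::rnbinom(length(mu), size = config$dispersion,
                                      mu = mu),
                       nrow = n, ncol = config$n_genes)
      cell_ids <- sprintf("%s_cell_%05d", ds_ids[d], seq_len(n))
      dimnames(counts) <- list(cell_ids, gene_ids)
      datasets[[d]] <- list(matrix = counts, cell_ids = cell_ids,
                            true_label = true_leaf,
                            observed_label = true_leaf)
    }
    structure(list(datasets = datasets, gene_ids = gene_ids,
                   markers = markers, ontology = ontology, config = config),
              class = "simulated_corpus")
  })
}

#' Distort annotations across datasets
#'
#' Injects the two cross-dataset annotation error modes: in
#' granularity-distorted datasets every cell's observed label is the parent
#' of its true leaf (hierarchical error); in synonym-using datasets, leaves
#' that have an alternate label are recorded under it (synonym error);
#' elsewhere observed = true leaf. Which datasets are distorted is drawn
#' (deterministically under the config seed) and recorded in the returned
#' corpus's `distortion` element.
#'
#' @param corpus A [simulate_expression()] result.
#' @param config The corpus's [simulation_config()].
#' @return The corpus with `observed_label` rewritten and a `distortion`
#'   record (`granularity_datasets`, `synonym_datasets`).
#' @export
apply_annotation_distortion <- function(corpus, config = corpus$config) {
  stopifnot(inherits(corpus, "simulated_corpus"))
  ds_ids <- names(corpus$datasets)
  n_gran <- as.integer(round_half_up(config$granularity_fraction * length(ds_ids)))
  picks <- with_seed(derive_seed(config$seed, 21L), {
    gran <- if (n_gran > 0) sort(sample(ds_ids, n_gran)) else character(0)
    rest <- setdiff(ds_ids, gran)
    syn <- if (config$n_synonym_datasets > 0 && length(rest) > 0) {
      sort(sample(rest, min(config$n_synonym_datasets, length(rest))))
    } else {
      character(0)
    }
    list(gran = gran, syn = syn)
  })
  leaf_parent <- corpus$ontology$leaf_parent
  synonyms <- corpus$ontology$synonyms
  for (d in ds_ids) {
    true <- corpus$datasets[[d]]$true_label
    obs <- true
    if (d %in% picks$gran) {
      obs <- unname(leaf_parent[true])
    } else if (d %in% picks$syn) {
      has_syn <- true %in% names(synonyms)
      obs[has_syn] <- unname(synonyms[true[has_syn]])
    }
    corpus$datasets[[d]]$observed_label <- obs
  }
  corpus$distortion <- list(granularity_datasets = picks$gran,
                            synonym_datasets = picks$syn)
  corpus
}

#' Generate a complete annotated corpus
#'
#' [simulate_ontology()] + [simulate_expression()] +
#' [apply_annotation_distortion()] in one call.
#'
#' @param config A [simulation_config()].
#' @return A distorted `simulated_corpus`.
#' @export
simulate_corpus <- function(config = simulation_config()) {
  onto <- simulate_ontology(config)
  corpus <- simulate_expression(config, onto)
  apply_annotation_distortion(corpus, config)
}

#' @export
print.simulated_corpus <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<simulated_corpus> %d datasets x %d cells, %d genes, %d leaf / %d parent types, %d synonym pair(s)\n",
    cfg$n_datasets, cfg$cells_per_dataset, cfg$n_genes, cfg$n_leaf_types,
    cfg$n_parent_types, cfg$n_synonym_pairs))
  if (!is.null(x$distortion)) {
    cat(sprintf("  granularity datasets: %s\n  synonym datasets: %s\n",
                paste(x$distortion$granularity_datasets, collapse = ", "),
                paste(x$distortion$synonym_datasets, collapse = ", ")))
  }
  invisible(x)
}

#' Total cells the generator emitted
#'
#' Bookkeeping used by conservation checks against the chunk store.
#'
#' @param corpus A `simulated_corpus`.
#' @return Integer cell count.
#' @export
corpus_cell_count <- function(corpus) {
  sum(vapply(corpus$datasets, function(d) nrow(d$matrix), integer(1)))
}

#' Chunk a simulated corpus into an on-disk store
#'
#' Runs the ingest path ([chunk_cells()]) on the corpus's observed labels.
#'
#' @param corpus A distorted `simulated_corpus`.
#' @param dir Store root directory.
#' @param chunk_size Cells per chunk; default 100.
#' @return A [chunk_store()].
#' @export
corpus_to_store <- function(corpus, dir, chunk_size = 100) {
  datasets <- lapply(corpus$datasets, function(d) {
    list(matrix = d$matrix, cell_ids = d$cell_ids, labels = d$observed_label)
  })
  chunk_cells(datasets, corpus$gene_ids, dir, chunk_size = chunk_size)
}

#' Export a simulated corpus as MTX datasets + curated edge table
#'
#' Writes one MTX + TSV-sidecar dataset directory per simulated dataset
#' (see [write_expression()]; matrices are stored genes x cells), plus
#' `edges.tsv` (the curated relationship table) and `truth.tsv` (true leaf
#' label, observed label and distortion kind per cell).
#'
#' @param corpus A distorted `simulated_corpus`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ds in names(corpus$datasets)) {
    d <- corpus$datasets[[ds]]
    write_expression(t(d$matrix), corpus$gene_ids, d$cell_ids,
                     data.frame(cell_id = d$cell_ids, dataset_id = ds,
                                cell_type = d$observed_label),
                     file.path(dir, ds))
  }
  utils::write.table(corpus$ontology$edge_table, file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- do.call(rbind, lapply(names(corpus$datasets), function(ds) {
    d <- corpus$datasets[[ds]]
    kind <- if (ds %in% corpus$distortion$granularity_datasets) "granularity"
            else if (ds %in% corpus$distortion$synonym_datasets) "synonym"
            else "none"
    data.frame(cell_id = d$cell_ids, dataset_id = ds,
               true_label = d$true_label, observed_label = d$observed_label,
               distortion = kind)
  }))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
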