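# Corpus handling: expression I/O, gene alignment, chunking, splits.
#
# A chunk store is an on-disk corpus partitioned into fixed-size blocks of
# cells (default 100, which is also the training batch size). Each chunk is a
# MatrixMarket file (cells x genes) plus a TSV of per-cell metadata; a JSON
# manifest records chunk order, dataset membership and cell counts. Chunks
# belonging to one dataset are contiguous in the manifest.

#' Load an expression dataset from MatrixMarket + TSV sidecars
#'
#' Expects `matrix.mtx` (genes x cells, coordinate format), `genes.tsv` (one
#' gene id per line), `barcodes.tsv` (one cell id per line) and
#' `metadata.tsv` (tab-separated, columns `cell_id`, `dataset_id`,
#' `cell_type`) inside `dir`.
#'
#' @param dir Directory containing the four files.
#' @return A list with `matrix` (genes x cells, dgCMatrix), `gene_ids`,
#'   `cell_ids` and `metadata` (data.frame aligned to cells).
#' @export
load_expression <- function(dir) {
  mtx_path <- file.path(dir, "matrix.mtx")
  for (f in c("matrix.mtx", "genes.tsv", "barcodes.tsv", "metadata.tsv")) {
    if (!file.exists(file.path(dir, f))) {
      stop_fmt("expression directory %s is missing %s", dir, f)
    }
  }
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  gene_ids <- readLines(file.path(dir, "genes.tsv"))
  cell_ids <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(m) != length(gene_ids) || ncol(m) != length(cell_ids)) {
    stop_fmt("matrix is %d x %d but sidecars give %d genes and %d cells",
             nrow(m), ncol(m), length(gene_ids), length(cell_ids))
  }
  meta <- utils::read.delim(file.path(dir, "metadata.tsv"), sep = "\t",
                            header = TRUE, colClasses = "character", quote = "")
  for (col in c("cell_id", "dataset_id", "cell_type")) {
    if (!col %in% names(meta)) {
      stop_fmt("metadata.tsv is missing column '%s'", col)
    }
  }
  if (nrow(meta) != length(cell_ids)) {
    stop_fmt("metadata has %d rows but barcodes list %d cells",
             nrow(meta), length(cell_ids))
  }
  meta <- meta[match(cell_ids, meta$cell_id), , drop = FALSE]
  if (anyNA(meta$cell_id)) stop_fmt("metadata cell_id does not cover barcodes")
  dimnames(m) <- list(gene_ids, cell_ids)
  list(matrix = m, gene_ids = gene_ids, cell_ids = cell_ids, metadata = meta)
}

#' Write an expression dataset as MatrixMarket + TSV sidecars
#'
#' Inverse of [load_expression()]; used by the simulator's disk export and in
#' round-trip tests.
#'
#' @param matrix Genes x cells matrix (dense or sparse).
#' @param gene_ids,cell_ids Identifiers matching the matrix dimensions.
#' @param metadata Data.frame with `cell_id`, `dataset_id`, `cell_type`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression <- function(matrix, gene_ids, cell_ids, metadata, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(matrix, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(gene_ids, file.path(dir, "genes.tsv"))
  writeLines(cell_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Align a dataset's genes to a fixed vocabulary
#'
#' Reorders the gene dimension to the vocabulary order, zero-fills vocabulary
#' genes the dataset lacks, and drops dataset genes outside the vocabulary.
#' Values of shared genes are untouched.
#'
#' @param matrix Cells x genes matrix.
#' @param gene_ids Gene identifiers for the columns of `matrix`.
#' @param vocab Ordered character vector of vocabulary gene ids (the model's
#'   fixed input layer).
#' @param verbose Report how many genes were zero-filled / dropped.
#' @return Cells x `length(vocab)` matrix in vocabulary order.
#' @export
align_genes <- function(matrix, gene_ids, vocab, verbose = FALSE) {
  if (length(gene_ids) != ncol(matrix)) {
    stop_fmt("gene_ids length (%d) does not match matrix columns (%d)",
             length(gene_ids), ncol(matrix))
  }
  idx <- match(vocab, gene_ids)
  n_missing <- sum(is.na(idx))
  if (n_missing == length(vocab)) {
    stop_fmt("no overlap between dataset genes and vocabulary")
  }
  out <- base::matrix(0, nrow = nrow(matrix), ncol = length(vocab),
                      dimnames = list(rownames(matrix), vocab))
  present <- !is.na(idx)
  out[, present] <- as.matrix(matrix[, idx[present], drop = FALSE])
  if (verbose) {
    message(sprintf("align_genes: %d vocabulary gene(s) zero-filled, %d dataset gene(s) dropped",
                    n_missing, length(gene_ids) - sum(present)))
  }
  out
}

#' Optional count normalization
#'
#' Counts-per-10k followed by log1p, the conventional scRNA-seq scaling; the
#' pipeline otherwise uses values as provided.
#'
#' @param matrix Cells x genes non-negative matrix.
#' @return Matrix of the same shape.
#' @export
normalize_log1p_cp10k <- function(matrix) {
  totals <- rowSums(matrix)
  totals[totals == 0] <- 1
  log1p(matrix / totals * 1e4)
}

#' Chunk aligned datasets into a fixed-size on-disk store
#'
#' Splits each dataset's cells into consecutive blocks of `chunk_size` (the
#' last block of a dataset may be smaller), writes each block as
#' MatrixMarket + metadata TSV under `dir`, and records a JSON manifest.
#' Every cell lands in exactly one chunk and a dataset's chunks are
#' contiguous.
#'
#' @param datasets Named list (names = dataset ids); each element a list with
#'   `matrix` (cells x G, already vocabulary-aligned), `cell_ids` and
#'   `labels` (one raw cell-type label per cell).
#' @param gene_ids The vocabulary the matrices are aligned to.
#' @param dir Store root directory.
#' @param chunk_size Cells per chunk; default 100.
#' @return A `chunk_store` object (see [chunk_store()]).
#' @export
chunk_cells <- function(datasets, gene_ids, dir, chunk_size = 100) {
  if (chunk_size < 1) stop_fmt("chunk_size must be >= 1")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  k <- 0L
  for (ds in names(datasets)) {
    d <- datasets[[ds]]
    if (ncol(d$matrix) != length(gene_ids)) {
      stop_fmt("dataset %s has %d gene columns; vocabulary has %d",
               ds, ncol(d$matrix), length(gene_ids))
    }
    n <- nrow(d$matrix)
    starts <- seq(1L, n, by = chunk_size)
    for (s in starts) {
      e <- min(s + chunk_size - 1L, n)
      k <- k + 1L
      stem <- sprintf("chunk_%05d", k)
      idx <- s:e
      Matrix::writeMM(
        methods::as(methods::as(Matrix::Matrix(d$matrix[idx, , drop = FALSE],
                                               sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix"),
        file.path(dir, paste0(stem, ".mtx")))
      utils::write.table(
        data.frame(cell_id = d$cell_ids[idx], dataset_id = ds,
                   cell_type = d$labels[idx]),
        file.path(dir, paste0(stem, ".cells.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      manifest[[k]] <- list(file = stem, dataset_id = ds,
                            n_cells = length(idx))
    }
  }
  writeLines(gene_ids, file.path(dir, "genes.tsv"))
  jsonlite::write_json(
    list(chunk_size = chunk_size, chunks = manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  chunk_store(dir)
}

#' Open a chunk store
#'
#' @param dir Root directory of a store written by [chunk_cells()].
#' @return An object of class `chunk_store` with the manifest (`file`,
#'   `dataset_id`, `n_cells` per chunk), the gene vocabulary and the total
#'   cell count. Chunk contents are read lazily and cached in memory.
#' @export
chunk_store <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop_fmt("no manifest.json under %s", dir)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  chunks <- man$chunks
  structure(
    list(root = dir,
         chunk_size = man$chunk_size,
         manifest = data.frame(file = chunks$file,
                               dataset_id = chunks$dataset_id,
                               n_cells = as.integer(chunks$n_cells)),
         gene_ids = readLines(file.path(dir, "genes.tsv")),
         total_cells = sum(as.integer(chunks$n_cells)),
         cache = new.env(parent = emptyenv())),
    class = "chunk_store")
}

#' @export
print.chunk_store <- function(x, ...) {
  cat(sprintf("<chunk_store> %d chunks (size %d), %d cells, %d datasets, %d genes\n  root: %s\n",
              nrow(x$manifest), x$chunk_size, x$total_cells,
              length(unique(x$manifest$dataset_id)), length(x$gene_ids),
              x$root))
  invisible(x)
}

#' Read one chunk from a store
#'
#' @param store A [chunk_store()].
#' @param i Chunk index into the manifest.
#' @param cache Keep the decoded chunk in memory for later reads.
#' @return List with `matrix` (dense cells x G), `cell_ids`, `dataset_id`
#'   and `labels`.
#' @export
read_chunk <- function(store, i, cache = TRUE) {
  stem <- store$manifest$file[i]
  if (cache && !is.null(store$cache[[stem]])) return(store$cache[[stem]])
  m <- as.matrix(Matrix::readMM(file.path(store$root, paste0(stem, ".mtx"))))
  meta <- utils::read.delim(file.path(store$root, paste0(stem, ".cells.tsv")),
                            sep = "\t", header = TRUE,
                            colClasses = "character", quote = "")
  colnames(m) <- store$gene_ids
  rownames(m) <- meta$cell_id
  chunk <- list(matrix = m, cell_ids = meta$cell_id,
                dataset_id = store$manifest$dataset_id[i],
                labels = meta$cell_type)
  if (cache) store$cache[[stem]] <- chunk
  chunk
}

#' Per-cell metadata for a whole store, in manifest order
#'
#' @param store A [chunk_store()].
#' @return Data.frame with `cell_id`, `dataset_id`, `cell_type` and `chunk`
#'   (the owning chunk index), one row per cell in storage order.
#' @export
store_cell_table <- function(store) {
  parts <- lapply(seq_len(nrow(store$manifest)), function(i) {
    ch <- read_chunk(store, i)
    data.frame(cell_id = ch$cell_ids, dataset_id = ch$dataset_id,
               cell_type = ch$labels, chunk = i)
  })
  do.call(rbind, parts)
}

#' Gold-standard label matrix for a store
#'
#' Builds the raw single-label [label_matrix()] over all cells of the store,
#' in manifest order, against a fixed type universe.
#'
#' @param store A [chunk_store()].
#' @param type_ids Ordered output-label universe; defaults to the sorted set
#'   of labels observed in the store.
#' @return A raw-mode `label_matrix`.
#' @export
store_label_matrix <- function(store, type_ids = NULL) {
  tab <- store_cell_table(store)
  if (is.null(type_ids)) type_ids <- sort(unique(tab$cell_type))
  label_matrix(tab$cell_type, tab$cell_id, type_ids)
}

#' Split a corpus into train and test at the dataset level
#'
#' Whole datasets go to one side or the other, so no dataset contributes
#' cells to both; this is the split that exposes batch-driven overestimation.
#' The test side receives `round_half_up(test_fraction * n)` datasets, at
#' least 1, chosen uniformly at random under `seed`.
#'
#' @param dataset_ids Character vector of all dataset ids (order irrelevant).
#' @param test_fraction Fraction of datasets held out; default 0.2.
#' @param seed Integer seed; the split is deterministic given it.
#' @return An object of class `dataset_split`: list with `train_datasets`,
#'   `test_datasets` and `seed`.
#' @export
#' @examples
#' split_by_dataset(paste0("ds", 1:10), 0.2, seed = 1)
split_by_dataset <- function(dataset_ids, test_fraction = 0.2, seed) {
  dataset_ids <- unique(as.character(dataset_ids))
  n <- length(dataset_ids)
  if (n < 2) stop_fmt("cross-dataset evaluation needs >= 2 datasets, got %d", n)
  n_test <- max(1L, as.integer(round_half_up(test_fraction * n)))
  if (n_test >= n) stop_fmt("test fraction %.2f leaves no training dataset", test_fraction)
  test <- with_seed(seed, sample(dataset_ids, n_test))
  structure(list(train_datasets = sort(setdiff(dataset_ids, test)),
                 test_datasets = sort(test),
                 seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test (seed %d)\n  test: %s\n",
              length(x$train_datasets), length(x$test_datasets), x$seed,
              paste(x$test_datasets, collapse = ", ")))
  invisible(x)
}

#' Hold out validation chunks from a training set
#'
#' Chunk-granularity random holdout used for the best-epoch callback.
#'
#' @param chunk_idx Integer indices of the training chunks.
#' @param fraction Fraction of chunks held out; default 0.1.
#' @param seed Integer seed.
#' @return List with `train` and `validation` integer index vectors
#'   (disjoint, union = `chunk_idx`).
#' @export
validation_holdout <- function(chunk_idx, fraction = 0.1, seed) {
  if (length(chunk_idx) < 2) stop_fmt("need >= 2 chunks to hold out validation")
  n_val <- as.integer(round_half_up(fraction * length(chunk_idx)))
  if (n_val == 0) {
    warning("empty validation holdout: best-epoch callback degenerates to the last epoch")
    return(list(train = chunk_idx, validation = integer(0)))
  }
  val <- with_seed(seed, sort(sample(chunk_idx, n_val)))
  list(train = setdiff(chunk_idx, val), validation = val)
}
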