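# Per-cell-type evaluation and cross-validation drivers.
#
# Every cell type is evaluated independently: the type's score column is
# ranked against the type's gold column, ignoring all other columns. A cell
# gold-annotated to both a type A and its parent A' counts as a positive in
# both columns; a prediction that supports A' but not A is a correct case
# for A' and a wrong case for A. Types whose gold column is single-class in
# a fold are recorded as ineligible (undefined metric), never scored 0.5.

#' Area under the ROC curve for one cell type
#'
#' Midrank Mann-Whitney estimator: the fraction of (positive, negative)
#' score pairs where the positive outranks the negative, ties counted half.
#'
#' @param scores Numeric per-cell scores for the type.
#' @param gold Binary (0/1 or logical) per-cell gold labels for the type.
#' @return AUC in `[0, 1]`, or `NA` when gold is single-class (the metric is
#'   undefined and the type is ineligible in that fold).
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))  # 1
roc_auc <- function(scores, gold) {
  gold <- as.integer(as.logical(gold))
  stopifnot(length(scores) == length(gold))
  n_pos <- sum(gold == 1L)
  n_neg <- sum(gold == 0L)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[gold == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve for one cell type
#'
#' Average-precision estimator over the ranked unique score thresholds
#' (step-wise summation, ties grouped, no interpolation):
#' `AP = sum_k (R_k - R_{k-1}) P_k` over descending thresholds k.
#'
#' @inheritParams roc_auc
#' @return AUPRC in `[0, 1]`, or `NA` when gold is single-class.
#' @export
#' @examples
#' auprc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0))  # prevalence: 0.5
auprc <- function(scores, gold) {
  gold <- as.integer(as.logical(gold))
  stopifnot(length(scores) == length(gold))
  n_pos <- sum(gold == 1L)
  if (n_pos == 0 || n_pos == length(gold)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; g <- gold[o]
  grp_pos <- rowsum(g, group = s, reorder = FALSE)[, 1]
  grp_n <- rowsum(rep(1L, length(g)), group = s, reorder = FALSE)[, 1]
  tp <- cumsum(grp_pos)
  pred_pos <- cumsum(grp_n)
  precision <- tp / pred_pos
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate a fitted model on a fold's test chunks
#'
#' Scores the test cells and computes per-type AUC/AUPRC against the gold
#' standard, one type at a time, restricted to types that carry at least one
#' positive cell in the fold's training gold (types never seen in training
#' cannot be evaluated).
#'
#' @param model A fitted [fit_celltype_nn()].
#' @param store A [chunk_store()].
#' @param test_chunks Manifest indices of the fold's test chunks.
#' @param gold A [label_matrix()] over the whole store, in the mode the
#'   model was trained with.
#' @param train_types Character vector of types present in the fold's
#'   training gold; defaults to types positive in the non-test cells.
#' @return Data.frame with one row per evaluable type: `type_id`, `auc`,
#'   `auprc` (`NA` when single-class in test), `n_pos`, `n_neg`.
#' @export
evaluate_fold <- function(model, store, test_chunks, gold,
                          train_types = NULL) {
  man <- store$manifest
  row_end <- cumsum(man$n_cells)
  row_start <- row_end - man$n_cells + 1L
  test_rows <- unlist(lapply(test_chunks, function(i) row_start[i]:row_end[i]))
  if (is.null(train_types)) {
    train_rows <- setdiff(seq_len(store$total_cells), test_rows)
    train_types <- colnames(gold)[colSums(unclass(gold)[train_rows, , drop = FALSE]) > 0]
  }
  scores <- predict(model, store, chunks = test_chunks)
  gold_test <- unclass(gold)[test_rows, , drop = FALSE]

  types <- intersect(model$type_ids, train_types)
  res <- lapply(types, function(ty) {
    y <- gold_test[, ty]
    data.frame(type_id = ty,
               auc = roc_auc(scores[, ty], y),
               auprc = auprc(scores[, ty], y),
               n_pos = sum(y == 1L), n_neg = sum(y == 0L))
  })
  do.call(rbind, res)
}

cv_default_config <- function(store, labels, mode, seed, config = NULL) {
  activation <- if (mode == "corrected") "sigmoid" else "softmax"
  if (is.null(config)) {
    model_config(input_dim = length(store$gene_ids),
                 output_dim = ncol(labels),
                 output_activation = activation, seed = seed)
  } else {
    config$input_dim <- length(store$gene_ids)
    config$output_dim <- ncol(labels)
    config$output_activation <- activation
    config$seed <- seed
    config
  }
}

new_evaluation_report <- function(metrics, folds, mode, split_level,
                                  n_folds, test_fraction, min_evaluations,
                                  seed) {
  structure(list(metrics = metrics, folds = folds, mode = mode,
                 split_level = split_level, n_folds = n_folds,
                 test_fraction = test_fraction,
                 min_evaluations = min_evaluations, seed = seed),
            class = "evaluation_report")
}

#' Cross-dataset cross-validation
#'
#' Repeats `n_folds` times: draw a fresh random 80/20 split of whole
#' datasets, train the classifier on the training datasets (raw single-label
#' gold with softmax, or ontology-propagated multi-label gold with sigmoid),
#' and evaluate per type on the held-out datasets. Because each iteration
#' redraws the split, this is Monte-Carlo cross-validation over datasets,
#' not a disjoint partition. Fully deterministic given `seed`.
#'
#' @param store A [chunk_store()].
#' @param labels Raw single-label [label_matrix()] for the store's cells.
#' @param graph A [cell_type_graph()]; required for `mode = "corrected"`.
#' @param mode `"raw"` (labels used as annotated) or `"corrected"`
#'   (annotations propagated through the ontology before training and
#'   evaluation).
#' @param n_folds Number of random-split iterations; default 10.
#' @param test_fraction Fraction of datasets held out per fold; default 0.2.
#' @param min_evaluations A type must have a defined AUC in at least this
#'   many folds to enter the summary median; default 5.
#' @param config Optional [model_config()] template (widths, epochs, ...);
#'   dims, activation and per-fold seed are set by the driver.
#' @param validation_fraction Training-chunk fraction held out for the
#'   best-epoch callback; default 0.1.
#' @param seed Integer master seed.
#' @param verbose Print per-fold progress.
#' @return An `evaluation_report`; see [summary.evaluation_report()].
#' @export
cross_dataset_cv <- function(store, labels, graph = NULL,
                             mode = c("raw", "corrected"),
                             n_folds = 10, test_fraction = 0.2,
                             min_evaluations = 5, config = NULL,
                             validation_fraction = 0.1, seed = 1,
                             verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(label_mode(labels) == "raw")
  gold <- if (mode == "corrected") {
    if (is.null(graph)) stop_fmt("mode 'corrected' needs a cell_type_graph")
    propagate_label_matrix(labels, graph)
  } else {
    labels
  }
  datasets <- unique(store$manifest$dataset_id)
  man <- store$manifest
  row_end <- cumsum(man$n_cells)
  row_start <- row_end - man$n_cells + 1L

  metrics <- list(); folds <- list()
  for (f in seq_len(n_folds)) {
    split <- split_by_dataset(datasets, test_fraction,
                              seed = derive_seed(seed, 1000L + f))
    cfg <- cv_default_config(store, gold, mode,
                             seed = derive_seed(seed, 2000L + f), config)
    model <- fit_celltype_nn(store, gold, split, cfg,
                             validation_fraction = validation_fraction)
    test_chunks <- which(man$dataset_id %in% split$test_datasets)
    train_rows <- unlist(lapply(which(man$dataset_id %in% split$train_datasets),
                                function(i) row_start[i]:row_end[i]))
    train_types <- colnames(gold)[colSums(unclass(gold)[train_rows, , drop = FALSE]) > 0]
    fm <- evaluate_fold(model, store, test_chunks, gold, train_types)
    fm$fold <- f
    metrics[[f]] <- fm
    folds[[f]] <- list(fold = f, train_datasets = split$train_datasets,
                       test_datasets = split$test_datasets,
                       best_epoch = model$best_epoch)
    if (verbose) {
      message(sprintf("fold %d/%d [%s]: test = {%s}, median AUC = %.3f",
                      f, n_folds, mode,
                      paste(split$test_datasets, collapse = ", "),
                      stats::median(fm$auc, na.rm = TRUE)))
    }
  }
  new_evaluation_report(do.call(rbind, metrics), folds, mode,
                        split_level = "dataset", n_folds, test_fraction,
                        min_evaluations, seed)
}

#' Cross-cell cross-validation
#'
#' Identical protocol to [cross_dataset_cv()] except the random split is
#' drawn over chunks of cells, ignoring dataset boundaries, so cells from
#' the same dataset appear on both sides. Provided to demonstrate the
#' batch-effect-driven overestimation this split produces.
#'
#' @inheritParams cross_dataset_cv
#' @return An `evaluation_report` with `split_level = "cell"`.
#' @export
cross_cell_cv <- function(store, labels, graph = NULL,
                          mode = c("raw", "corrected"),
                          n_folds = 10, test_fraction = 0.2,
                          min_evaluations = 5, config = NULL,
                          validation_fraction = 0.1, seed = 1,
                          verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(label_mode(labels) == "raw")
  gold <- if (mode == "corrected") {
    if (is.null(graph)) stop_fmt("mode 'corrected' needs a cell_type_graph")
    propagate_label_matrix(labels, graph)
  } else {
    labels
  }
  man <- store$manifest
  n_chunks <- nrow(man)
  row_end <- cumsum(man$n_cells)
  row_start <- row_end - man$n_cells + 1L

  metrics <- list(); folds <- list()
  for (f in seq_len(n_folds)) {
    n_test <- max(1L, as.integer(round_half_up(test_fraction * n_chunks)))
    test_chunks <- with_seed(derive_seed(seed, 3000L + f),
                             sort(sample(seq_len(n_chunks), n_test)))
    train_chunks <- setdiff(seq_len(n_chunks), test_chunks)
    cfg <- cv_default_config(store, gold, mode,
                             seed = derive_seed(seed, 2000L + f), config)
    model <- fit_nn_chunks(store, gold, train_chunks, cfg,
                           validation_fraction = validation_fraction)
    train_rows <- unlist(lapply(train_chunks, function(i) row_start[i]:row_end[i]))
    train_types <- colnames(gold)[colSums(unclass(gold)[train_rows, , drop = FALSE]) > 0]
    fm <- evaluate_fold(model, store, test_chunks, gold, train_types)
    fm$fold <- f
    metrics[[f]] <- fm
    folds[[f]] <- list(fold = f, test_chunks = test_chunks,
                       best_epoch = model$best_epoch)
    if (verbose) {
      message(sprintf("fold %d/%d [cell-level, %s]: median AUC = %.3f",
                      f, n_folds, mode, stats::median(fm$auc, na.rm = TRUE)))
    }
  }
  new_evaluation_report(do.call(rbind, metrics), folds, mode,
                        split_level = "cell", n_folds, test_fraction,
                        min_evaluations, seed)
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- summary(x)
  cat(sprintf(
    "<evaluation_report> %s-level %d-fold CV, mode = %s\n  %d types evaluated, %d eligible (>= %d evaluations)\n  median AUC over eligible types: %.4f\n",
    x$split_level, x$n_folds, x$mode, nrow(s$per_type),
    sum(s$per_type$eligible), x$min_evaluations, s$median_auc))
  invisible(x)
}

#' Summarize an evaluation report
#'
#' Aggregates per-fold, per-type AUC/AUPRC. The headline statistic is the
#' median, over types with at least `min_evaluations` defined AUCs across
#' folds, of each type's across-fold mean AUC. Per-fold medians are also
#' reported, since the aggregation order matters and both views are useful.
#'
#' @param object An `evaluation_report`.
#' @param min_evaluations Override the report's eligibility threshold.
#' @param ... Unused.
#' @return A list of class `evaluation_summary`: `per_type` (data.frame),
#'   `per_fold` (data.frame), `median_auc` (headline), `median_auprc` and
#'   `median_of_fold_medians`.
#' @export
summary.evaluation_report <- function(object,
                                      min_evaluations = object$min_evaluations,
                                      ...) {
  m <- object$metrics
  sp <- split(m, m$type_id)
  per_type <- do.call(rbind, lapply(sp, function(d) {
    data.frame(type_id = d$type_id[1],
               n_evals = sum(!is.na(d$auc)),
               mean_auc = mean(d$auc, na.rm = TRUE),
               median_auc = stats::median(d$auc, na.rm = TRUE),
               mean_auprc = mean(d$auprc, na.rm = TRUE),
               median_auprc = stats::median(d$auprc, na.rm = TRUE))
  }))
  per_type$eligible <- per_type$n_evals >= min_evaluations
  rownames(per_type) <- NULL

  sf <- split(m, m$fold)
  per_fold <- do.call(rbind, lapply(sf, function(d) {
    data.frame(fold = d$fold[1],
               n_types = sum(!is.na(d$auc)),
               median_auc = stats::median(d$auc, na.rm = TRUE),
               median_auprc = stats::median(d$auprc, na.rm = TRUE))
  }))
  rownames(per_fold) <- NULL

  elig <- per_type[per_type$eligible, , drop = FALSE]
  structure(list(per_type = per_type, per_fold = per_fold,
                 median_auc = stats::median(elig$mean_auc),
                 median_auprc = stats::median(elig$mean_auprc),
                 median_of_fold_medians = stats::median(per_fold$median_auc),
                 min_evaluations = min_evaluations, mode = object$mode,
                 split_level = object$split_level),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("Evaluation summary (%s-level CV, mode = %s)\n",
              x$split_level, x$mode))
  cat(sprintf("  eligible types (>= %d evaluations): %d of %d\n",
              x$min_evaluations, sum(x$per_type$eligible), nrow(x$per_type)))
  cat(sprintf("  median AUC   (across-fold mean, then median over types): %.4f\n",
              x$median_auc))
  cat(sprintf("  median AUPRC (same aggregation):                         %.4f\n",
              x$median_auprc))
  cat(sprintf("  median of per-fold median AUCs:                          %.4f\n",
              x$median_of_fold_medians))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `per_type_metrics.tsv` (fold-level rows), `summary.tsv` (per-type
#' aggregates) and `config.yaml` (protocol echo) under `dir`.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- summary(report)
  utils::write.table(report$metrics, file.path(dir, "per_type_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(s$per_type, file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- list(mode = report$mode, split_level = report$split_level,
              n_folds = report$n_folds, test_fraction = report$test_fraction,
              min_evaluations = report$min_evaluations, seed = report$seed,
              median_auc = s$median_auc)
  writeLines(yaml::as.yaml(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
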