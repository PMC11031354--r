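# Model archives: a directory of portable text artifacts.

#' Save a fitted classifier as a model archive
#'
#' Writes `config.yaml`, per-layer weight tables (`W_<l>.tsv`, `b_<l>.tsv`),
#' `gene_vocab.tsv`, `type_ids.tsv` and `training_log.tsv` under `dir`.
#' Everything is plain text, so archives are portable and diffable.
#'
#' @param model A fitted [fit_celltype_nn()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_celltype_nn <- function(model, dir) {
  stopifnot(inherits(model, "celltype_nn"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- model$config
  meta <- list(
    input_dim = cfg$input_dim, output_dim = cfg$output_dim,
    hidden_widths = cfg$hidden_widths,
    output_activation = cfg$output_activation,
    learning_rate = cfg$learning_rate,
    adam_beta1 = cfg$adam_beta1, adam_beta2 = cfg$adam_beta2,
    epochs = cfg$epochs, batch_size = cfg$batch_size, seed = cfg$seed,
    best_epoch = model$best_epoch, label_mode = model$label_mode,
    n_layers = length(model$layers),
    train_datasets = as.list(model$train_datasets))
  writeLines(yaml::as.yaml(meta), file.path(dir, "config.yaml"))
  for (l in seq_along(model$layers)) {
    utils::write.table(model$layers[[l]]$W,
                       file.path(dir, sprintf("W_%d.tsv", l)),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines(format(model$layers[[l]]$b, digits = 17),
               file.path(dir, sprintf("b_%d.tsv", l)))
  }
  writeLines(model$gene_ids, file.path(dir, "gene_vocab.tsv"))
  writeLines(model$type_ids, file.path(dir, "type_ids.tsv"))
  utils::write.table(model$training_log, file.path(dir, "training_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a model archive
#'
#' @param dir A directory written by [save_celltype_nn()].
#' @return A `celltype_nn` usable with [predict.celltype_nn()].
#' @export
load_celltype_nn <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- model_config(meta$input_dim, meta$output_dim,
                      hidden_widths = unlist(meta$hidden_widths),
                      output_activation = meta$output_activation,
                      learning_rate = meta$learning_rate,
                      adam_beta1 = meta$adam_beta1,
                      adam_beta2 = meta$adam_beta2,
                      epochs = meta$epochs, batch_size = meta$batch_size,
                      seed = meta$seed)
  layers <- lapply(seq_len(meta$n_layers), function(l) {
    list(W = as.matrix(utils::read.table(
           file.path(dir, sprintf("W_%d.tsv", l)), sep = "\t")),
         b = as.numeric(readLines(file.path(dir, sprintf("b_%d.tsv", l)))))
  })
  layers <- lapply(layers, function(ly) { dimnames(ly$W) <- NULL; ly })
  structure(
    list(config = cfg, layers = layers, best_epoch = meta$best_epoch,
         training_log = utils::read.delim(file.path(dir, "training_log.tsv")),
         gene_ids = readLines(file.path(dir, "gene_vocab.tsv")),
         type_ids = readLines(file.path(dir, "type_ids.tsv")),
         label_mode = meta$label_mode,
         train_datasets = unlist(meta$train_datasets)),
    class = "celltype_nn")
}
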