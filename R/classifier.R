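# Fully connected multi-output cell-type classifier.
#
# Architecture: input layer of G genes, rectified-linear hidden layers
# (default 256/128/64), and an output unit per cell type. The output
# activation is softmax with categorical cross-entropy when the gold standard
# is single-label, or sigmoid with per-type binary cross-entropy when it is
# multi-label (ontology-propagated), in which case a cell may be predicted to
# several types at once. Optimized with Adam (lr 3e-5, beta1 0.9, beta2
# 0.999) over 100-cell chunk batches for 20 epochs; the returned weights are
# those of the epoch with minimal loss on a held-out validation set
# (best-epoch callback).

#' Classifier configuration
#'
#' @param input_dim Number of input genes G.
#' @param output_dim Number of output cell types M.
#' @param hidden_widths Hidden layer widths; default `c(256, 128, 64)`. A
#'   deeper alternative `c(512, 256, 128, 64)` gives similar performance.
#' @param output_activation `"softmax"` (single-label gold standard,
#'   categorical cross-entropy) or `"sigmoid"` (multi-label gold standard,
#'   binary cross-entropy per type).
#' @param learning_rate,adam_beta1,adam_beta2 Adam optimizer settings;
#'   defaults 3e-5, 0.9, 0.999.
#' @param epochs Training epochs; default 20.
#' @param batch_size Cells per batch; equals the chunk size of the store
#'   (default 100) since chunks are the batching unit.
#' @param seed Integer seed controlling weight initialization and the
#'   per-epoch chunk visiting order.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_dim, output_dim,
                         hidden_widths = c(256L, 128L, 64L),
                         output_activation = c("softmax", "sigmoid"),
                         learning_rate = 3e-5,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         epochs = 20L, batch_size = 100L, seed = 1L) {
  output_activation <- match.arg(output_activation)
  if (any(hidden_widths < 1)) stop_fmt("hidden widths must be positive")
  if (input_dim < 1 || output_dim < 1) stop_fmt("input and output dims must be positive")
  if (epochs < 1) stop_fmt("training needs at least 1 epoch to select from")
  structure(list(input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim),
                 hidden_widths = as.integer(hidden_widths),
                 output_activation = output_activation,
                 learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "model_config")
}

LOSS_EPS <- 1e-12

#' Categorical cross-entropy loss
#'
#' `-sum_c y_c log(p_c)` per cell, natural log, with scores clipped to
#' `[1e-12, 1]` before the log. `y` is a one-hot row over M types and `p` a
#' softmax score row.
#'
#' @param y Binary vector or cells x M matrix (one 1 per row).
#' @param p Score vector or matrix of the same shape.
#' @return Non-negative numeric, one value per cell.
#' @export
#' @examples
#' cross_entropy_loss(c(0, 1, 0), c(0.25, 0.5, 0.25))  # ln 2
cross_entropy_loss <- function(y, p) {
  y <- rbind(y); p <- rbind(p)
  stopifnot(all(dim(y) == dim(p)))
  p <- pmin(pmax(p, LOSS_EPS), 1)
  as.numeric(-rowSums(y * log(p)))
}

#' Binary cross-entropy loss summed over types
#'
#' `-sum_c [y_c log(p_c) + (1 - y_c) log(1 - p_c)]` per cell, the standard
#' pairing for sigmoid multi-label outputs; scores clipped to
#' `[1e-12, 1 - 1e-12]`.
#'
#' @inheritParams cross_entropy_loss
#' @return Non-negative numeric, one value per cell.
#' @export
#' @examples
#' binary_cross_entropy_loss(c(1, 0), c(0.5, 0.5))  # 2 ln 2
binary_cross_entropy_loss <- function(y, p) {
  y <- rbind(y); p <- rbind(p)
  stopifnot(all(dim(y) == dim(p)))
  p <- pmin(pmax(p, LOSS_EPS), 1 - LOSS_EPS)
  as.numeric(-rowSums(y * log(p) + (1 - y) * log1p(-p)))
}

# --- internal network machinery -------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Glorot-style variance-scaled uniform init, seeded.
init_weights <- function(dims, seed) {
  with_seed(seed, {
    lapply(seq_len(length(dims) - 1), function(l) {
      fan_in <- dims[l]; fan_out <- dims[l + 1]
      lim <- sqrt(6 / (fan_in + fan_out))
      list(W = matrix(stats::runif(fan_in * fan_out, -lim, lim),
                      fan_in, fan_out),
           b = rep(0, fan_out))
    })
  })
}

nn_forward <- function(X, layers, activation) {
  acts <- vector("list", length(layers))
  A <- X
  for (l in seq_along(layers)) {
    Z <- A %*% layers[[l]]$W  # fresh buffer; in-place kernels may own it
    add_bias_inplace(Z, layers[[l]]$b)
    if (l < length(layers)) {
      relu_inplace(Z)
      A <- Z
    } else {
      A <- if (activation == "softmax") softmax_rows(Z) else sigmoid(Z)
    }
    acts[[l]] <- A
  }
  acts
}

# Gradients of the mean per-cell loss. For both softmax+CE and sigmoid+BCE
# the output-layer gradient reduces to (p - y) / n.
nn_backward <- function(X, Y, layers, acts) {
  n <- nrow(X)
  L <- length(layers)
  grads <- vector("list", L)
  delta <- (acts[[L]] - Y) / n
  for (l in L:1) {
    A_prev <- if (l == 1) X else acts[[l - 1]]
    grads[[l]] <- list(W = crossprod(A_prev, delta), b = colSums(delta))
    if (l > 1) {
      delta <- tcrossprod(delta, layers[[l]]$W)
      delta <- delta * (acts[[l - 1]] > 0)  # ReLU derivative
    }
  }
  grads
}

adam_state_init <- function(layers) {
  lapply(layers, function(ly) list(mW = ly$W * 0, vW = ly$W * 0,
                                   mb = ly$b * 0, vb = ly$b * 0))
}

# Mutates layers and state in place (the trainer deep-copies before any
# snapshot leaves the loop).
adam_update <- function(layers, grads, state, t, lr, b1, b2, eps = 1e-8) {
  c1 <- 1 - b1^t
  c2 <- 1 - b2^t
  for (l in seq_along(layers)) {
    adam_step_inplace(layers[[l]]$W, grads[[l]]$W,
                      state[[l]]$mW, state[[l]]$vW, lr, b1, b2, c1, c2, eps)
    adam_step_inplace(layers[[l]]$b, grads[[l]]$b,
                      state[[l]]$mb, state[[l]]$vb, lr, b1, b2, c1, c2, eps)
  }
  invisible(NULL)
}

deep_copy_layers <- function(layers) {
  lapply(layers, function(ly) list(W = ly$W + 0, b = ly$b + 0))
}

mean_loss <- function(Y, P, activation) {
  if (activation == "softmax") mean(cross_entropy_loss(Y, P))
  else mean(binary_cross_entropy_loss(Y, P))
}

# --- fitting ----------------------------------------------------------------

#' Fit the cell-type classifier on a chunked corpus
#'
#' Trains the fully connected network on the training datasets of `split`,
#' holding out a fraction of training chunks for the best-epoch callback.
#' The gold standard's mode must match the configured output activation:
#' raw single-label with softmax, propagated multi-label with sigmoid.
#' Training is reproducible given `config$seed` (same initialization, same
#' chunk visiting order, same holdout).
#'
#' @param store A [chunk_store()] whose gene vocabulary matches
#'   `config$input_dim`.
#' @param labels A [label_matrix()] covering the store's cells in manifest
#'   order.
#' @param split A [split_by_dataset()] result; only chunks of
#'   `train_datasets` are visited.
#' @param config A [model_config()].
#' @param validation_fraction Fraction of training chunks held out for
#'   epoch selection; default 0.1.
#' @return An object of class `celltype_nn`: the fitted model carrying the
#'   weights of the epoch with minimal validation loss, the per-epoch
#'   train/validation loss trace, and the type/gene universes.
#' @seealso [predict.celltype_nn()], [cross_dataset_cv()]
#' @export
fit_celltype_nn <- function(store, labels, split, config,
                            validation_fraction = 0.1) {
  stopifnot(inherits(store, "chunk_store"), inherits(labels, "label_matrix"),
            inherits(split, "dataset_split"), inherits(config, "model_config"))
  mode <- label_mode(labels)
  want <- if (config$output_activation == "softmax") "raw" else "propagated"
  if (mode != want) {
    stop_fmt("label mode '%s' does not match output activation '%s' (expected '%s' labels)",
             mode, config$output_activation, want)
  }
  if (nrow(labels) != store$total_cells) {
    stop_fmt("label matrix has %d rows but the store holds %d cells",
             nrow(labels), store$total_cells)
  }
  if (length(store$gene_ids) != config$input_dim) {
    stop_fmt("store vocabulary (%d genes) does not match input_dim (%d)",
             length(store$gene_ids), config$input_dim)
  }
  if (ncol(labels) != config$output_dim) {
    stop_fmt("label universe (%d types) does not match output_dim (%d)",
             ncol(labels), config$output_dim)
  }

  train_all <- which(store$manifest$dataset_id %in% split$train_datasets)
  if (length(train_all) == 0) stop_fmt("empty training set")
  fit_nn_chunks(store, labels, train_all, config, validation_fraction,
                train_datasets = split$train_datasets)
}

# Core training loop over an explicit set of training chunk indices; shared
# by the dataset-level and cell-level cross-validation drivers.
fit_nn_chunks <- function(store, labels, train_all, config,
                          validation_fraction = 0.1,
                          train_datasets = NULL) {
  mode <- label_mode(labels)
  man <- store$manifest
  row_end <- cumsum(man$n_cells)
  row_start <- row_end - man$n_cells + 1L
  hold <- validation_holdout(train_all, validation_fraction,
                             seed = derive_seed(config$seed, 1L))
  train_idx <- hold$train
  val_idx <- hold$validation

  chunk_xy <- function(i) {
    ch <- read_chunk(store, i)
    rows <- row_start[i]:row_end[i]
    list(X = ch$matrix, Y = unclass(labels)[rows, , drop = FALSE])
  }

  dims <- c(config$input_dim, config$hidden_widths, config$output_dim)
  layers <- init_weights(dims, seed = derive_seed(config$seed, 2L))
  state <- adam_state_init(layers)
  act <- config$output_activation

  val_data <- lapply(val_idx, chunk_xy)
  val_loss_of <- function(ly) {
    if (length(val_data) == 0) return(NA_real_)
    tot <- 0; n <- 0
    for (d in val_data) {
      P <- nn_forward(d$X, ly, act)[[length(ly)]]
      tot <- tot + sum(if (act == "softmax") cross_entropy_loss(d$Y, P)
                       else binary_cross_entropy_loss(d$Y, P))
      n <- n + nrow(d$X)
    }
    tot / n
  }

  log_epoch <- integer(0); log_train <- numeric(0); log_val <- numeric(0)
  best <- list(epoch = NA_integer_, loss = Inf, layers = NULL)
  t <- 0L
  for (epoch in seq_len(config$epochs)) {
    order_ <- with_seed(derive_seed(config$seed, 100L + epoch),
                        sample(train_idx))
    ep_tot <- 0; ep_n <- 0
    for (i in order_) {
      d <- chunk_xy(i)
      acts <- nn_forward(d$X, layers, act)
      P <- acts[[length(layers)]]
      ep_tot <- ep_tot + sum(if (act == "softmax") cross_entropy_loss(d$Y, P)
                             else binary_cross_entropy_loss(d$Y, P))
      ep_n <- ep_n + nrow(d$X)
      grads <- nn_backward(d$X, d$Y, layers, acts)
      t <- t + 1L
      adam_update(layers, grads, state, t, config$learning_rate,
                  config$adam_beta1, config$adam_beta2)
    }
    vl <- val_loss_of(layers)
    log_epoch <- c(log_epoch, epoch)
    log_train <- c(log_train, ep_tot / ep_n)
    log_val <- c(log_val, vl)
    if (!is.na(vl) && vl < best$loss) {
      best <- list(epoch = epoch, loss = vl, layers = deep_copy_layers(layers))
    }
  }
  if (is.na(best$epoch)) {  # no validation set: fall back to final weights
    best <- list(epoch = config$epochs, loss = NA_real_, layers = layers)
  }

  structure(
    list(config = config,
         layers = best$layers,
         best_epoch = best$epoch,
         training_log = data.frame(epoch = log_epoch,
                                   train_loss = log_train,
                                   val_loss = log_val),
         gene_ids = store$gene_ids,
         type_ids = colnames(labels),
         label_mode = mode,
         train_datasets = train_datasets %||%
           sort(unique(man$dataset_id[train_all])),
         train_chunks = train_all,
         validation_chunks = val_idx),
    class = "celltype_nn")
}

#' Predict cell-type scores
#'
#' @param object A fitted [fit_celltype_nn()] model.
#' @param newdata A cells x G expression matrix aligned to the model's gene
#'   vocabulary, or a [chunk_store()] (optionally with `chunks` restricting
#'   which manifest entries to score).
#' @param chunks Optional integer chunk indices when `newdata` is a store.
#' @param ... Unused.
#' @return A cells x M score matrix in `[0, 1]`; rows sum to 1 under softmax,
#'   entries are independent per-type probabilities under sigmoid.
#' @export
predict.celltype_nn <- function(object, newdata, chunks = NULL, ...) {
  if (inherits(newdata, "chunk_store")) {
    idx <- chunks %||% seq_len(nrow(newdata$manifest))
    X <- do.call(rbind, lapply(idx, function(i) read_chunk(newdata, i)$matrix))
  } else {
    X <- as.matrix(newdata)
  }
  if (ncol(X) != object$config$input_dim) {
    stop_fmt("newdata has %d gene columns; model expects %d",
             ncol(X), object$config$input_dim)
  }
  P <- nn_forward(X, object$layers, object$config$output_activation)[[length(object$layers)]]
  dimnames(P) <- list(rownames(X), object$type_ids)
  P
}

#' Score every cell of a chunk store
#'
#' Convenience wrapper over [predict.celltype_nn()] returning one score row
#' per cell in manifest order.
#'
#' @inheritParams predict.celltype_nn
#' @param store A [chunk_store()].
#' @param chunks Optional manifest indices.
#' @return Cells x M score matrix.
#' @export
predict_scores <- function(object, store, chunks = NULL) {
  predict(object, store, chunks = chunks)
}

#' @export
print.celltype_nn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<celltype_nn> %d genes -> [%s] -> %d types (%s)\n  best epoch %d/%d, validation loss %.4f\n",
    cfg$input_dim, paste(cfg$hidden_widths, collapse = ", "), cfg$output_dim,
    cfg$output_activation, x$best_epoch, cfg$epochs,
    x$training_log$val_loss[x$best_epoch]))
  invisible(x)
}

#' @export
summary.celltype_nn <- function(object, ...) {
  print(object)
  cat(sprintf("  trained on %d dataset(s): %s\n",
              length(object$train_datasets),
              paste(object$train_datasets, collapse = ", ")))
  cat(sprintf("  optimizer: Adam lr=%g beta1=%g beta2=%g, %d epochs, batch %d\n",
              object$config$learning_rate, object$config$adam_beta1,
              object$config$adam_beta2, object$config$epochs,
              object$config$batch_size))
  invisible(object$training_log)
}

#' @export
coef.celltype_nn <- function(object, ...) object$layers

#' Plot the training and validation loss trace
#'
#' @param x A fitted `celltype_nn`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.celltype_nn <- function(x, ...) {
  log <- x$training_log
  graphics::matplot(log$epoch, cbind(log$train_loss, log$val_loss),
                    type = "b", pch = c(1, 19), lty = 1,
                    xlab = "epoch", ylab = "mean per-cell loss",
                    col = c("grey40", "firebrick"), ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 19),
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
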