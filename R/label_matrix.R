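# Binary gold-standard label matrices (cells x types).

new_label_matrix <- function(m, mode, dropped_types = character()) {
  structure(m, class = c("label_matrix", class(m)),
            label_mode = mode, dropped_types = dropped_types)
}

#' Build a binary cells-by-types gold-standard matrix
#'
#' In `"raw"` mode every cell carries exactly one label (one 1 per row); after
#' [propagate_label_matrix()] the matrix is in `"propagated"` mode and rows may
#' carry several 1s (the annotation closure of the raw label).
#'
#' @param labels Character vector, one raw cell-type label per cell.
#' @param cell_ids Character vector of cell identifiers (row names).
#' @param type_ids Ordered character vector of the model's output labels
#'   (column universe). Labels in `labels` must all be present.
#' @return An integer matrix of class `label_matrix` with `label_mode`
#'   attribute `"raw"`.
#' @export
#' @examples
#' lm <- label_matrix(c("T cell", "B cell"), c("c1", "c2"),
#'                    c("B cell", "T cell", "lymphocyte"))
#' rowSums(lm)
label_matrix <- function(labels, cell_ids, type_ids) {
  labels <- trimws(as.character(labels))
  if (length(labels) != length(cell_ids)) {
    stop_fmt("labels (%d) and cell_ids (%d) differ in length",
             length(labels), length(cell_ids))
  }
  if (anyDuplicated(type_ids)) stop_fmt("type_ids must be unique")
  unknown <- setdiff(unique(labels), type_ids)
  if (length(unknown) > 0) {
    stop_fmt("label(s) absent from type_ids: %s",
             paste(unknown, collapse = ", "))
  }
  m <- matrix(0L, nrow = length(labels), ncol = length(type_ids),
              dimnames = list(as.character(cell_ids), as.character(type_ids)))
  m[cbind(seq_along(labels), match(labels, type_ids))] <- 1L
  new_label_matrix(m, mode = "raw")
}

#' Annotation mode of a label matrix
#'
#' @param x A `label_matrix`.
#' @return `"raw"` (single-label) or `"propagated"` (multi-label).
#' @export
label_mode <- function(x) attr(x, "label_mode")

# Raw per-cell label from a single-label matrix.
raw_label_of <- function(labmat) {
  colnames(labmat)[max.col(labmat, ties.method = "first")]
}

#' @export
print.label_matrix <- function(x, ...) {
  cat(sprintf("<label_matrix> %d cells x %d types, mode = %s\n",
              nrow(x), ncol(x), label_mode(x)))
  invisible(x)
}

# Subset rows, preserving class and attributes.
subset_label_matrix <- function(labmat, idx) {
  new_label_matrix(unclass(labmat)[idx, , drop = FALSE],
                   mode = label_mode(labmat),
                   dropped_types = attr(labmat, "dropped_types"))
}
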