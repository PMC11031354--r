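# Cell-type ontology graph and annotation propagation.
#
# The graph is a curated set of directed relations between cell-type label
# strings: `parent` edges point from a child type to a parent type (is-a), and
# `synonym` edges connect two labels for the same biological type (stored
# symmetrized, one directed edge each way). Propagating a cell's annotation
# means taking everything reachable from its raw label along parent edges
# (child-to-parent direction) and synonym edges (both directions), to a
# fixpoint.

#' Construct a cell-type relationship graph
#'
#' Builds the directed graph used to propagate cell annotations. Synonym
#' edges are symmetrized, duplicate edges collapsed and labels
#' whitespace-trimmed. Self-loop rows are rejected.
#'
#' @param edges A data.frame with character columns `child`, `parent` and
#'   `relation` (`"parent"` or `"synonym"`). For a `parent` row the edge runs
#'   child -> parent; for a `synonym` row both directions are added.
#' @param nodes Optional character vector of extra node labels to include
#'   even if they appear in no edge.
#'
#' @return An object of class `cell_type_graph`: a list with elements
#'   `nodes` (character), `edges` (data.frame `from`, `to`, `kind`) and
#'   `adjacency` (named list mapping each node to the labels reachable in one
#'   step).
#' @seealso [load_edge_table()], [propagate_labels()]
#' @export
#' @examples
#' g <- cell_type_graph(data.frame(
#'   child = c("ciliated epithelial cell", "ciliated epithelial cell"),
#'   parent = c("ciliated cell", "epithelial cell"),
#'   relation = c("parent", "parent")
#' ))
#' propagate_labels("ciliated epithelial cell", g)
cell_type_graph <- function(edges, nodes = character()) {
  required <- c("child", "parent", "relation")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    stop_fmt("edge table is missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  child <- trimws(as.character(edges$child))
  parent <- trimws(as.character(edges$parent))
  relation <- trimws(as.character(edges$relation))

  bad_rel <- !relation %in% c("parent", "synonym")
  if (any(bad_rel)) {
    stop_fmt("unknown relation kind(s): %s (rows %s)",
             paste(unique(relation[bad_rel]), collapse = ", "),
             paste(which(bad_rel), collapse = ", "))
  }
  loops <- child == parent
  if (any(loops)) {
    stop_fmt("self-loop edge(s) rejected at row(s): %s",
             paste(which(loops), collapse = ", "))
  }

  from <- child
  to <- parent
  kind <- relation
  syn <- relation == "synonym"
  if (any(syn)) {
    from <- c(from, parent[syn])
    to <- c(to, child[syn])
    kind <- c(kind, rep("synonym", sum(syn)))
  }
  edf <- unique(data.frame(from = from, to = to, kind = kind,
                           stringsAsFactors = FALSE))

  all_nodes <- sort(unique(c(edf$from, edf$to, trimws(as.character(nodes)))))
  adjacency <- split(edf$to, factor(edf$from, levels = all_nodes))
  adjacency <- lapply(adjacency, unique)

  structure(
    list(nodes = all_nodes, edges = edf, adjacency = adjacency),
    class = "cell_type_graph"
  )
}

#' Read a curated cell-type relationship table
#'
#' Parses a TSV of child-parent and synonym relations into a
#' [cell_type_graph()]. The file must have a header; by default the columns
#' are `child`, `parent` and `relation`, but other column names can be mapped
#' via `dialect`.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param dialect Named character vector mapping the canonical column names
#'   (`child`, `parent`, `relation`) to the names used in the file.
#' @param verbose Emit a parse report (node and per-kind edge counts).
#' @return A `cell_type_graph`.
#' @export
#' @examples
#' tab <- system.file("extdata", "example_cell_type_relations.tsv",
#'                    package = "ontoAnnot")
#' g <- load_edge_table(tab, verbose = FALSE)
#' propagate_labels("lung ciliated cell", g)
load_edge_table <- function(path,
                            dialect = c(child = "child", parent = "parent",
                                        relation = "relation"),
                            verbose = TRUE) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  for (canon in c("child", "parent", "relation")) {
    src <- dialect[[canon]] %||% canon
    if (!src %in% names(tab)) {
      stop_fmt("edge table %s is missing column '%s'", path, src)
    }
    names(tab)[names(tab) == src] <- canon
  }
  g <- cell_type_graph(tab[, c("child", "parent", "relation")])
  if (verbose) {
    kinds <- table(g$edges$kind)
    message(sprintf(
      "cell-type graph: %d nodes, %d parent edge(s), %d synonym edge(s) (directed)",
      length(g$nodes), kinds["parent"] %||% 0L,
      if ("synonym" %in% names(kinds)) kinds[["synonym"]] else 0L))
  }
  g
}

#' @export
print.cell_type_graph <- function(x, ...) {
  kinds <- table(factor(x$edges$kind, levels = c("parent", "synonym")))
  cat(sprintf(
    "<cell_type_graph> %d nodes, %d parent edges, %d directed synonym edges\n",
    length(x$nodes), kinds[["parent"]], kinds[["synonym"]]))
  invisible(x)
}

#' Propagate a cell's annotation through the ontology graph
#'
#' Returns the annotation closure of `labels`: every label reachable from any
#' raw label by following parent edges upward and synonym edges in both
#' directions, iterated to a fixpoint. The result is always a superset of the
#' input and propagating it again returns itself. Labels absent from the graph
#' propagate to themselves only (the curated table cannot be assumed
#' complete); they are counted in the `off_graph` attribute.
#'
#' @param labels Character vector of raw cell-type labels (an annotation set
#'   for one cell).
#' @param graph A [cell_type_graph()].
#' @return Sorted character vector of propagated labels, with attribute
#'   `off_graph` giving the input labels not present in the graph.
#' @export
propagate_labels <- function(labels, graph) {
  stopifnot(inherits(graph, "cell_type_graph"))
  labels <- unique(trimws(as.character(labels)))
  if (length(labels) == 0) {
    stop_fmt("an annotated cell must carry at least one label")
  }
  off <- setdiff(labels, graph$nodes)

  seen <- labels
  frontier <- intersect(labels, graph$nodes)
  while (length(frontier) > 0) {
    nxt <- unique(unlist(graph$adjacency[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  structure(sort(seen), off_graph = off)
}

# Closure of every node (plus requested off-graph labels), as a named list.
# Shared by propagate_label_matrix and the simulator consistency checks.
label_closures <- function(labels, graph) {
  labels <- unique(labels)
  out <- lapply(labels, function(l) as.character(propagate_labels(l, graph)))
  names(out) <- labels
  out
}

#' Propagate a gold-standard label matrix
#'
#' Rewrites each row of a [label_matrix()] to the ontology closure of its
#' support, restricted to the matrix's type universe. The usual input is a
#' raw single-label matrix; an already-propagated matrix is accepted and
#' passes through unchanged (closures are closed under propagation), so the
#' operation is idempotent. Types produced by propagation but absent from
#' the matrix columns are dropped and reported via the `dropped_types`
#' attribute.
#'
#' @param labmat A `label_matrix`.
#' @param graph A [cell_type_graph()].
#' @param verbose Report dropped propagated types and off-graph labels.
#' @return A `label_matrix` in `"propagated"` mode with the same cells and
#'   type columns.
#' @export
propagate_label_matrix <- function(labmat, graph, verbose = FALSE) {
  stopifnot(inherits(labmat, "label_matrix"))
  type_ids <- colnames(labmat)
  m_in <- unclass(labmat)
  # distinct row supports, encoded as label strings, so closures are
  # computed once per support rather than per cell
  support_key <- apply(m_in, 1, function(r) paste(which(r == 1L), collapse = ","))
  if (any(support_key == "")) stop_fmt("annotated cells must carry at least one label")
  closures <- lapply(unique(support_key), function(k) {
    labs <- type_ids[as.integer(strsplit(k, ",")[[1]])]
    as.character(propagate_labels(labs, graph))
  })
  names(closures) <- unique(support_key)

  dropped <- sort(unique(unlist(lapply(closures, setdiff, y = type_ids))))
  off <- setdiff(unique(unlist(lapply(closures, intersect, y = type_ids))),
                 graph$nodes)
  if (verbose) {
    if (length(dropped) > 0) {
      message("propagated type(s) outside the label universe dropped: ",
              paste(dropped, collapse = ", "))
    }
    if (length(off) > 0) {
      message(length(off), " off-graph label(s) propagate to themselves only")
    }
  }

  m <- matrix(0L, nrow = nrow(labmat), ncol = ncol(labmat),
              dimnames = dimnames(labmat))
  col_of <- stats::setNames(seq_along(type_ids), type_ids)
  for (k in names(closures)) {
    cols <- col_of[intersect(closures[[k]], type_ids)]
    m[support_key == k, cols] <- 1L
  }
  new_label_matrix(m, mode = "propagated", dropped_types = dropped)
}
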