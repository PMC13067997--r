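#' Create a taxonomy from a parent-pointer table
#'
#' A taxonomy is a rooted tree given as a parent-pointer table; the root
#' points to itself. Every document of an index maps to one node, and reads
#' can be classified to any node (a document's taxon or an ancestor).
#'
#' @param nodes Data.frame with columns `node_id` (integer), `parent_id`
#'   (integer), `rank` (character) and `name` (character).
#' @return Object of class `cbwt_taxonomy`.
#' @export
taxonomy <- function(nodes) {
  req <- c("node_id", "parent_id", "rank", "name")
  if (!all(req %in% names(nodes))) stop("missing taxonomy columns")
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (anyDuplicated(nodes$node_id)) stop("duplicate node IDs")
  root <- nodes$node_id[nodes$node_id == nodes$parent_id]
  if (length(root) != 1L) stop("taxonomy must have exactly one root")
  if (!all(nodes$parent_id %in% nodes$node_id))
    stop("parent_id refers to unknown node")
  structure(list(nodes = nodes, root = root), class = "cbwt_taxonomy")
}

#' @export
print.cbwt_taxonomy <- function(x, ...) {
  cat("Taxonomy:", nrow(x$nodes), "nodes, root =", x$root, "\n")
  invisible(x)
}

.tax_parent <- function(tax, node) {
  tax$nodes$parent_id[match(node, tax$nodes$node_id)]
}

#' Ancestors of a node (self first, root last)
#'
#' @param tax A [taxonomy()].
#' @param node Node ID.
#' @return Integer vector of node IDs from `node` up to the root.
#' @export
tax_ancestors <- function(tax, node) {
  if (is.na(node) || !(node %in% tax$nodes$node_id))
    stop("unknown taxonomy node: ", node)
  path <- node
  while (node != tax$root) {
    node <- .tax_parent(tax, node)
    path <- c(path, node)
    if (length(path) > nrow(tax$nodes)) stop("cycle in taxonomy")
  }
  path
}

#' Lowest common ancestor of a set of nodes
#'
#' @param tax A [taxonomy()].
#' @param nodes Integer vector of node IDs (non-empty).
#' @return The node ID of the LCA; a single node is its own LCA.
#' @export
tax_lca <- function(tax, nodes) {
  nodes <- unique(as.integer(nodes))
  if (length(nodes) == 0L) stop("LCA of an empty node set is undefined")
  anc <- tax_ancestors(tax, nodes[1L])
  for (nd in nodes[-1L]) {
    anc <- anc[anc %in% tax_ancestors(tax, nd)]
  }
  anc[1L]
}

#' Ancestor of a node at a given rank
#'
#' Walks from the node toward the root (including the node itself) until a
#' node with rank `rank` is found.
#'
#' @param tax A [taxonomy()].
#' @param node Node ID.
#' @param rank Rank label, e.g. `"species"`.
#' @return The ancestor's node ID, or `NA` if no ancestor has that rank
#'   (e.g. the node lies above the rank).
#' @export
tax_ancestor_at_rank <- function(tax, node, rank) {
  path <- tax_ancestors(tax, node)
  ranks <- tax$nodes$rank[match(path, tax$nodes$node_id)]
  hit <- which(ranks == rank)
  if (length(hit) == 0L) NA_integer_ else path[hit[1L]]
}

#' Is one node a strict ancestor of another?
#'
#' @param tax A [taxonomy()].
#' @param a Candidate ancestor node ID.
#' @param b Descendant node ID.
#' @return `TRUE` iff `a` is a strict (proper) ancestor of `b`.
#' @export
tax_is_ancestor <- function(tax, a, b) {
  a != b && a %in% tax_ancestors(tax, b)
}

#' Rank of a node
#'
#' @param tax A [taxonomy()].
#' @param node Node ID(s).
#' @return Character vector of rank labels.
#' @export
tax_rank <- function(tax, node) {
  tax$nodes$rank[match(node, tax$nodes$node_id)]
}

#' Read a taxonomy from a parent-pointer TSV
#'
#' Expected columns (with header): `node_id`, `parent_id`, `rank`, `name`;
#' the root points to itself.
#'
#' @param path TSV file path.
#' @return A [taxonomy()].
#' @export
read_taxonomy <- function(path) {
  taxonomy(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a taxonomy to a parent-pointer TSV
#'
#' @param tax A [taxonomy()].
#' @param path Output file path.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
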