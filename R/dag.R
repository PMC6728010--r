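# Directed acyclic graphs as logical adjacency matrices.
# amat[i, j] is TRUE when there is a directed edge  nodes[i] -> nodes[j].

#' Construct a directed acyclic graph
#'
#' Builds a DAG over a named node set from an edge list. Edges are ordered
#' pairs `tail -> head`; self-loops, duplicate edges, and directed cycles are
#' rejected.
#'
#' @param nodes character vector of node names (unique, non-empty).
#' @param edges a two-column matrix or data.frame of (tail, head) node names,
#'   or `NULL` for the empty graph.
#' @return An object of class `"guardnet_dag"`: a list with `nodes` and the
#'   logical adjacency matrix `amat`.
#' @examples
#' g <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' dag_edges(g)
#' @export
dag <- function(nodes, edges = NULL) {
  stopifnot(is.character(nodes), length(nodes) >= 1, !anyDuplicated(nodes))
  amat <- matrix(FALSE, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns (tail, head)")
    bad <- !(edges %in% nodes)
    if (any(bad)) stop("unknown node(s) in edges: ",
                       paste(unique(edges[bad]), collapse = ", "))
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    key <- paste(edges[, 1], edges[, 2])
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
    amat[edges] <- TRUE
  }
  g <- structure(list(nodes = nodes, amat = amat), class = "guardnet_dag")
  if (!is_acyclic(amat)) stop("edge set contains a directed cycle")
  g
}

#' @export
print.guardnet_dag <- function(x, ...) {
  e <- dag_edges(x)
  cat("DAG with", length(x$nodes), "nodes and", nrow(e), "edges\n")
  if (nrow(e) > 0)
    cat(paste0("  ", e[, 1], " -> ", e[, 2], collapse = "\n"), "\n")
  invisible(x)
}

#' Edge list of a DAG
#' @param g a `guardnet_dag`.
#' @return character matrix with columns `tail`, `head`, one row per edge.
#' @export
dag_edges <- function(g) {
  idx <- which(g$amat, arr.ind = TRUE)
  out <- cbind(tail = g$nodes[idx[, 1]], head = g$nodes[idx[, 2]])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Parents of a node
#' @param g a `guardnet_dag`.
#' @param node node name.
#' @return character vector of parent node names.
#' @export
dag_parents <- function(g, node) {
  g$nodes[g$amat[, node]]
}

# Acyclicity by repeated removal of sink-free nodes (Kahn).
is_acyclic <- function(amat) {
  n <- nrow(amat)
  indeg <- colSums(amat)
  active <- rep(TRUE, n)
  repeat {
    src <- which(active & indeg == 0)
    if (length(src) == 0) break
    for (s in src) {
      active[s] <- FALSE
      ch <- which(amat[s, ])
      indeg[ch] <- indeg[ch] - 1
    }
  }
  !any(active)
}

#' Topological order of a DAG
#' @param g a `guardnet_dag`.
#' @return node names in an order where every edge points forward.
#' @export
topological_order <- function(g) {
  amat <- g$amat
  n <- nrow(amat)
  indeg <- colSums(amat)
  active <- rep(TRUE, n)
  ord <- character(0)
  while (length(ord) < n) {
    src <- which(active & indeg == 0)
    if (length(src) == 0) stop("graph is cyclic")
    s <- src[1]  # deterministic: first in node order
    ord <- c(ord, g$nodes[s])
    active[s] <- FALSE
    indeg[s] <- NA
    ch <- which(amat[s, ])
    indeg[ch] <- indeg[ch] - 1
  }
  ord
}

# TRUE if a directed path from `from` to `to` exists (indices into amat).
has_directed_path <- function(amat, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(nrow(amat))
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(amat[v, ] & !seen))
  }
  FALSE
}

#' Test whether two nodes are connected ignoring edge direction,
#' optionally after deleting a set of nodes.
#' @param g a `guardnet_dag`.
#' @param from,to node names.
#' @param removing node names deleted from the graph before the search.
#' @return logical.
#' @export
dag_connected <- function(g, from, to, removing = character(0)) {
  keep <- setdiff(g$nodes, removing)
  if (!(from %in% keep) || !(to %in% keep)) return(FALSE)
  sk <- g$amat[keep, keep, drop = FALSE]
  sk <- sk | t(sk)
  i <- match(from, keep); j <- match(to, keep)
  seen <- logical(length(keep))
  stack <- i
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v == j) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(sk[v, ] & !seen))
  }
  FALSE
}
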