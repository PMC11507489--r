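#' Directed acyclic graph over named variables
#'
#' Minimal DAG container used for learned structures. Edges are ordered
#' (parent, child) pairs; self-loops, duplicate edges and directed cycles are
#' rejected at construction.
#'
#' @param nodes character vector of node names (unique, non-empty).
#' @param edges two-column character matrix (or data.frame) of
#'   (parent, child) pairs; may have zero rows.
#' @return an object of class `dag` with fields `nodes` and `edges`.
#' @export
dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes) || any(!nzchar(nodes)))
    stop("node names must be unique and non-empty")
  edges <- normalize_edges(edges)
  check_edges(nodes, edges, acyclic = TRUE)
  structure(list(nodes = nodes, edges = edges), class = "dag")
}

#' Directed graph, cycles allowed
#'
#' Container for the MAP summary graph: each variable pair contributes at most
#' one directed edge independently, so the result need not be acyclic.
#'
#' @inheritParams dag
#' @return an object of class `digraph`.
#' @export
digraph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes) || any(!nzchar(nodes)))
    stop("node names must be unique and non-empty")
  edges <- normalize_edges(edges)
  check_edges(nodes, edges, acyclic = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "digraph")
}

normalize_edges <- function(edges) {
  if (is.null(edges) || NROW(edges) == 0L) {
    m <- matrix(character(0), 0, 2)
  } else {
    m <- as.matrix(edges)
    if (ncol(m) != 2L) stop("edges must have two columns (parent, child)")
    storage.mode(m) <- "character"
  }
  colnames(m) <- c("from", "to")
  rownames(m) <- NULL
  m
}

check_edges <- function(nodes, edges, acyclic) {
  if (nrow(edges) == 0L) return(invisible(TRUE))
  if (!all(edges %in% nodes)) stop("edge endpoint not among nodes")
  if (any(edges[, 1] == edges[, 2])) stop("self-loop not allowed")
  if (anyDuplicated(paste(edges[, 1], edges[, 2], sep = "\r")))
    stop("duplicate edge")
  if (acyclic && is_cyclic(nodes, edges)) stop("graph contains a directed cycle")
  invisible(TRUE)
}

# Kahn's algorithm; TRUE if a directed cycle exists.
is_cyclic <- function(nodes, edges) {
  n <- length(nodes)
  if (nrow(edges) == 0L) return(FALSE)
  from <- match(edges[, 1], nodes)
  to <- match(edges[, 2], nodes)
  indeg <- tabulate(to, n)
  out <- split(to, from)
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    ch <- out[[as.character(v)]]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen < n
}

#' Topological order of a DAG
#'
#' @param g a [dag].
#' @return node names in an order where every parent precedes its children.
#' @export
topological_order <- function(g) {
  stopifnot(inherits(g, "dag"))
  nodes <- g$nodes
  edges <- g$edges
  n <- length(nodes)
  indeg <- tabulate(match(edges[, 2], nodes), n)
  order <- character(0)
  avail <- nodes[indeg == 0L]
  indeg <- stats::setNames(indeg, nodes)
  while (length(avail)) {
    avail <- sort(avail)            # deterministic among ties
    v <- avail[[1L]]; avail <- avail[-1L]
    order <- c(order, v)
    ch <- edges[edges[, 1] == v, 2]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
  }
  if (length(order) != n) stop("graph contains a directed cycle")
  order
}

#' Parents of a node
#'
#' @param g a [dag] or [digraph].
#' @param node node name.
#' @return character vector of parent names, sorted.
#' @export
parents <- function(g, node) {
  sort(unname(g$edges[g$edges[, 2] == node, 1]))
}

has_edge <- function(g, from, to) {
  any(g$edges[, 1] == from & g$edges[, 2] == to)
}

#' @export
print.dag <- function(x, ...) {
  cat("DAG:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges))
    cat(paste0("  ", x$edges[, 1], " -> ", x$edges[, 2], collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.digraph <- function(x, ...) {
  cat("Directed graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (cycles permitted)\n")
  if (nrow(x$edges))
    cat(paste0("  ", x$edges[, 1], " -> ", x$edges[, 2], collapse = "\n"), "\n")
  invisible(x)
}
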