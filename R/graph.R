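#' Simple undirected sampled graph
#'
#' Lightweight container for a simple undirected graph on `N` vertices:
#' an edge matrix of unordered distinct vertex pairs (1-based indices,
#' `u < v` after normalization). Self-loops and duplicate edges are
#' rejected.
#'
#' @param N vertex count.
#' @param edges two-column integer matrix of edges (may have zero rows).
#' @return An object of class `fcbm_graph` with components `N` and `edges`.
#' @examples
#' g <- fcbm_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
#' degree_sequence(g)
#' @export
fcbm_graph <- function(N, edges = matrix(integer(), 0, 2)) {
  N <- as.integer(N)
  if (N < 1L) stop("N must be positive", call. = FALSE)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L && nrow(edges) > 0L) {
    stop("edges must have two columns", call. = FALSE)
  }
  if (nrow(edges) > 0L) {
    storage.mode(edges) <- "integer"
    if (anyNA(edges) || any(edges < 1L) || any(edges > N)) {
      stop("edge endpoints out of range", call. = FALSE)
    }
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed", call. = FALSE)
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1]
    key <- (edges[, 1] - 1) * as.double(N) + edges[, 2]
    if (anyDuplicated(key)) stop("duplicate edges are not allowed", call. = FALSE)
    edges <- edges[order(key), , drop = FALSE]
  } else {
    edges <- matrix(integer(), 0, 2)
  }
  dimnames(edges) <- NULL
  structure(list(N = N, edges = edges), class = "fcbm_graph")
}

#' @export
print.fcbm_graph <- function(x, ...) {
  cat(sprintf(
    "Simple undirected graph: %d vertices, %d edges (mean degree %.4g)\n",
    x$N, nrow(x$edges), 2 * nrow(x$edges) / x$N
  ))
  invisible(x)
}

#' @rdname fcbm_graph
#' @param g an `fcbm_graph`
#' @export
degree_sequence <- function(g) {
  stopifnot(inherits(g, "fcbm_graph"))
  tabulate(g$edges, nbins = g$N)
}

#' Block-pair link counts of a graph
#'
#' Counts edges between every ordered pair of blocks; the diagonal stores
#' twice the intra-block edge count, matching the convention used for the
#' target matrix `K`.
#'
#' @param g an [fcbm_graph()].
#' @param part an [block_partition()].
#' @return Numeric `n x n` symmetric matrix `L_IJ`.
#' @export
block_link_counts <- function(g, part) {
  stopifnot(inherits(g, "fcbm_graph"), inherits(part, "fcbm_partition"))
  n <- part$n
  L <- matrix(0, n, n)
  if (nrow(g$edges) > 0L) {
    bi <- part$assignment[g$edges[, 1]]
    bj <- part$assignment[g$edges[, 2]]
    tab <- table(factor(bi, levels = seq_len(n)), factor(bj, levels = seq_len(n)))
    L <- unname(unclass(tab) + t(unclass(tab)))
    storage.mode(L) <- "double"
  }
  L
}

#' Convert to an igraph object
#'
#' @param g an [fcbm_graph()].
#' @return An `igraph` graph with the same vertices and edges.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "fcbm_graph"))
  ig <- igraph::make_empty_graph(n = g$N, directed = FALSE)
  igraph::add_edges(ig, as.vector(t(g$edges)))
}
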