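#' Sample a graph from an edge-probability model
#'
#' Draws a simple undirected graph by including each unordered vertex pair
#' `(i, j)`, `i < j`, independently with probability `p_ij` — the exact
#' sampling scheme implied by the factorized ensemble probability. Pairs
#' are processed block pair by block pair with vectorized Bernoulli draws
#' (chunked so that no more than a few million pairs are held at once),
#' which keeps memory linear in the output at `N = 10^4` and beyond.
#'
#' @param model an [edge_model()].
#' @param seed optional integer seed; fixed seed gives a reproducible
#'   graph.
#' @return An [fcbm_graph()].
#' @export
sample_graph <- function(model, seed = NULL) {
  stopifnot(inherits(model, "fcbm_model"))
  if (!is.null(seed)) set.seed(seed)
  part <- model$part
  # below ~5000 vertices the full pair-probability table fits comfortably
  # in memory; it is built once per model and reused across draws
  if (as.double(part$N)^2 <= 2.5e7) {
    tab <- pair_probability_table(model)
    keep <- stats::runif(length(tab$p)) < tab$p
    return(fcbm_graph(part$N, cbind(tab$i[keep], tab$j[keep])))
  }
  members <- block_members(part)
  x <- model$x
  y <- model$y
  chunk_limit <- 4e6
  out <- vector("list", part$n * (part$n + 1) / 2)
  used <- 0L
  for (I in seq_len(part$n)) {
    vi <- members[[I]]
    for (J in I:part$n) {
      if (y[I, J] == 0) next
      vj <- members[[J]]
      res <- sample_block_pair(
        x, y[I, J], vi, vj, I == J, model$mode, chunk_limit
      )
      if (!is.null(res)) {
        used <- used + 1L
        out[[used]] <- res
      }
    }
  }
  edges <- do.call(rbind, out[seq_len(used)])
  if (is.null(edges)) edges <- matrix(integer(), 0, 2)
  fcbm_graph(part$N, edges)
}

sample_block_pair <- function(x, y_ij, vi, vj, same_block, mode, chunk_limit) {
  if (same_block) {
    m <- length(vi)
    if (m < 2L) return(NULL)
    # chunk rows of the upper triangle
    rows_per_chunk <- max(1L, floor(chunk_limit / m))
    res <- list()
    r <- 1L
    while (r < m) {
      rr <- r:min(m - 1L, r + rows_per_chunk - 1L)
      # pairs (a, b) with a in rr, b > a
      a_idx <- rep(rr, times = m - rr)
      b_idx <- unlist(lapply(rr, function(u) (u + 1L):m), use.names = FALSE)
      p <- apply_prob_rule(x[vi[a_idx]] * x[vi[b_idx]] * y_ij, mode)
      keep <- stats::runif(length(p)) < p
      if (any(keep)) res[[length(res) + 1L]] <- cbind(vi[a_idx[keep]], vi[b_idx[keep]])
      r <- rr[length(rr)] + 1L
    }
    if (length(res) == 0L) NULL else do.call(rbind, res)
  } else {
    mi <- length(vi)
    mj <- length(vj)
    rows_per_chunk <- max(1L, floor(chunk_limit / mj))
    res <- list()
    r <- 1L
    while (r <= mi) {
      rr <- r:min(mi, r + rows_per_chunk - 1L)
      p <- apply_prob_rule(outer(x[vi[rr]], x[vj]) * y_ij, mode)
      keep <- which(stats::runif(length(p)) < p)
      if (length(keep) > 0L) {
        ai <- ((keep - 1L) %% length(rr)) + 1L
        bj <- ((keep - 1L) %/% length(rr)) + 1L
        res[[length(res) + 1L]] <- cbind(vi[rr[ai]], vj[bj])
      }
      r <- rr[length(rr)] + 1L
    }
    if (length(res) == 0L) NULL else do.call(rbind, res)
  }
}

# all unordered pairs with nonzero edge probability, as parallel vectors
# (i < j, probabilities after the model's rule); cached on the model
pair_probability_table <- function(model) {
  cache <- model$cache
  if (!is.null(cache$pair_table)) {
    return(cache$pair_table)
  }
  part <- model$part
  members <- block_members(part)
  x <- model$x
  y <- model$y
  ii <- list()
  jj <- list()
  pp <- list()
  s <- 0L
  for (I in seq_len(part$n)) {
    vi <- members[[I]]
    for (J in I:part$n) {
      if (y[I, J] == 0) next
      vj <- members[[J]]
      if (I == J) {
        if (length(vi) < 2L) next
        m <- outer(x[vi], x[vi]) * y[I, J]
        ut <- upper.tri(m)
        idx <- which(ut, arr.ind = TRUE)
        a <- vi[idx[, 1]]
        b <- vi[idx[, 2]]
        p <- apply_prob_rule(m[ut], model$mode)
      } else {
        m <- outer(x[vi], x[vj]) * y[I, J]
        a <- rep(vi, times = length(vj))
        b <- rep(vj, each = length(vi))
        p <- apply_prob_rule(as.vector(m), model$mode)
      }
      pos <- p > 0
      if (!any(pos)) next
      s <- s + 1L
      ii[[s]] <- a[pos]
      jj[[s]] <- b[pos]
      pp[[s]] <- p[pos]
    }
  }
  tab <- list(
    i = unlist(ii, use.names = FALSE),
    j = unlist(jj, use.names = FALSE),
    p = unlist(pp, use.names = FALSE)
  )
  if (is.null(tab$i)) tab <- list(i = integer(), j = integer(), p = numeric())
  cache$pair_table <- tab
  tab
}

#' Sample an ensemble of independent graphs
#'
#' Draws `n_graphs` independent graphs. A root seed deterministically
#' spawns one sub-seed per graph (recorded in the result), so ensembles
#' are reproducible from `(seed, n_graphs)` alone.
#'
#' @param model an [edge_model()].
#' @param n_graphs number of graphs (>= 1).
#' @param seed root integer seed.
#' @return List of [fcbm_graph()] objects with attribute `seeds`.
#' @export
sample_ensemble <- function(model, n_graphs, seed = NULL) {
  stopifnot(n_graphs >= 1)
  seeds <- derive_seeds(seed, n_graphs)
  graphs <- lapply(seq_len(n_graphs), function(i) sample_graph(model, seeds[[i]]))
  attr(graphs, "seeds") <- seeds
  graphs
}

# spawn per-stage / per-graph sub-seeds from one root seed
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Ensemble block statistics
#'
#' Empirical counterparts of the model constraints: mean block-pair link
#' counts (diagonal doubled) and mean degree sequence across an ensemble.
#'
#' @param graphs list of [fcbm_graph()] sharing `N`.
#' @param part an [block_partition()].
#' @return List with `L` (mean `n x n` link-count matrix) and `degree`
#'   (mean per-vertex degree).
#' @export
ensemble_block_statistics <- function(graphs, part) {
  stopifnot(length(graphs) >= 1L, inherits(part, "fcbm_partition"))
  L <- matrix(0, part$n, part$n)
  deg <- numeric(part$N)
  for (g in graphs) {
    stopifnot(inherits(g, "fcbm_graph"), g$N == part$N)
    L <- L + block_link_counts(g, part)
    deg <- deg + degree_sequence(g)
  }
  list(L = L / length(graphs), degree = deg / length(graphs))
}
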