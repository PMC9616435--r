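#' Constraint set for the maximum-entropy ensemble
#'
#' Bundles the soft (expectation) constraints defining a fitness-corrected
#' or degree-corrected block model: the `n x n` matrix `K` of target
#' expected link counts per block pair (diagonal stores twice the expected
#' intra-block edge count) and the per-vertex target expected degrees `k`.
#' Internal consistency requires `sum_J K_IJ == sum_{i in I} k_i` for every
#' block `I`; feasibility requires `0 <= k_i <= N - 1` and
#' `0 <= K_IJ <= N_IJ`, without which no distribution over simple graphs
#' can satisfy the constraints.
#'
#' @param K symmetric numeric `n x n` matrix of expected link counts.
#' @param k numeric vector of expected degrees (length `N`).
#' @param part an [block_partition()].
#' @param p optional density scalar in `(0, 1)` (present when the
#'   constraints were built from a density / mixing matrix / fitness
#'   triplet; absent in degree-corrected mode).
#' @param rel_tol relative tolerance for the consistency identity.
#' @return An object of class `fcbm_constraints` with components `K`, `k`,
#'   `p`, and `part`.
#' @export
constraint_set <- function(K, k, part, p = NULL, rel_tol = 1e-9) {
  stopifnot(inherits(part, "fcbm_partition"))
  K <- as.matrix(K)
  k <- as.numeric(k)
  n <- part$n
  N <- part$N
  if (!all(dim(K) == c(n, n))) stop("K has wrong dimensions", call. = FALSE)
  if (length(k) != N) stop("k has wrong length", call. = FALSE)
  if (any(!is.finite(K)) || any(!is.finite(k))) {
    stop("constraints must be finite", call. = FALSE)
  }
  if (max(abs(K - t(K))) > rel_tol * max(1, max(abs(K)))) {
    stop("K must be symmetric", call. = FALSE)
  }
  if (any(K < 0) || any(k < 0)) stop("constraints must be non-negative", call. = FALSE)
  if (any(k > N - 1 + 1e-9)) {
    stop("infeasible constraints: some k_i exceeds N - 1", call. = FALSE)
  }
  cap <- part$pair_counts
  if (any(K > cap + rel_tol * pmax(1, cap))) {
    stop("infeasible constraints: some K_IJ exceeds the pair count N_IJ",
      call. = FALSE
    )
  }
  if (!is.null(p)) {
    if (!(is.numeric(p) && length(p) == 1L && p > 0 && p < 1)) {
      stop("p must be a scalar in (0, 1)", call. = FALSE)
    }
  }
  # consistency identity: sum_J K_IJ = sum_{i in I} k_i for every block
  block_deg <- rowSums(K)
  k_block <- as.numeric(rowsum(k, part$assignment))
  gap <- abs(block_deg - k_block) / pmax(1, abs(block_deg))
  if (any(gap > rel_tol)) {
    stop(sprintf(
      "inconsistent constraints: max relative gap %.3g between row sums of K and block degree totals",
      max(gap)
    ), call. = FALSE)
  }
  structure(
    list(K = unname(K), k = k, p = p, part = part),
    class = "fcbm_constraints"
  )
}

#' @export
print.fcbm_constraints <- function(x, ...) {
  cat(sprintf(
    "FCBM constraint set: N = %d, n = %d blocks, total expected degree %.6g%s\n",
    x$part$N, x$part$n, sum(x$k),
    if (is.null(x$p)) "" else sprintf(", density p = %.6g", x$p)
  ))
  invisible(x)
}

#' Build fitness-corrected block-model constraints
#'
#' Translates the model parameters (density `p`, mixing-density matrix
#' `delta`, fitness vector `f`) into explicit expectation constraints:
#' \deqn{K_{IJ} = p \binom{N}{2} \Delta_{IJ}, \qquad
#'       k_i = p \binom{N}{2} \frac{f_i}{\sum_{u \in I_i} f_u}
#'             \sum_J \Delta_{I_i J}.}
#' The two families are consistent by construction
#' (`sum_J K_IJ == sum_{i in I} k_i`), and since `sum(delta) == 2` the total
#' expected degree is `p N (N - 1)`, i.e. the ensemble density is exactly
#' `p`. Fitness enters only through within-block shares, so rescaling `f`
#' by any positive constant leaves the result unchanged.
#'
#' @param p density scalar in `(0, 1)`.
#' @param delta mixing-density matrix (validated by [mixing_density()]).
#' @param f per-vertex fitness (strictly positive).
#' @param part an [block_partition()] with `n` matching `delta`.
#' @return An [constraint_set()] with `p` recorded.
#' @examples
#' part <- block_partition(rep(1:2, each = 2))
#' delta <- mixing_density(matrix(c(0.8, 0.2, 0.2, 0.8), 2))
#' cs <- build_constraints(0.1, delta, rep(1, 4), part)
#' cs$K
#' cs$k
#' @export
build_constraints <- function(p, delta, f, part) {
  stopifnot(inherits(part, "fcbm_partition"))
  if (!(is.numeric(p) && length(p) == 1L && p > 0 && p < 1)) {
    stop("p must be a scalar in (0, 1)", call. = FALSE)
  }
  delta <- mixing_density(unclass(delta))
  if (nrow(delta) != part$n) {
    stop("delta dimension does not match the number of blocks", call. = FALSE)
  }
  f <- fitness_vector(f)
  if (length(f) != part$N) stop("fitness length must equal N", call. = FALSE)
  half_pairs <- p * choose(part$N, 2)
  K <- half_pairs * unclass(delta)
  f_block <- as.numeric(rowsum(f, part$assignment))
  share <- f / f_block[part$assignment]
  k <- half_pairs * share * rowSums(delta)[part$assignment]
  constraint_set(K, k, part, p = p)
}

#' Constraints observed on a graph (degree-corrected mode)
#'
#' Reads the block-pair link counts and the degree sequence off an observed
#' graph, producing the constraint set whose maximum-entropy ensemble
#' randomizes that graph while preserving both families in expectation.
#' The diagonal of `K` stores twice the intra-block edge count.
#'
#' @param g an [fcbm_graph()].
#' @param part an [block_partition()] covering `g`'s vertices.
#' @return An [constraint_set()] with `p = NULL`.
#' @export
constraints_from_graph <- function(g, part) {
  stopifnot(inherits(g, "fcbm_graph"), inherits(part, "fcbm_partition"))
  if (g$N != part$N) stop("graph and partition sizes differ", call. = FALSE)
  constraint_set(block_link_counts(g, part), degree_sequence(g), part)
}

#' Density giving a target mean degree
#'
#' Inverts the mean-degree relation of the model: since the ordered sum of
#' `delta` is 2, the total expected degree is `p N (N - 1)`, so a target
#' mean degree `mu` corresponds to `p = mu / (N - 1)`.
#'
#' @param mu target mean degree, `0 < mu < N - 1`.
#' @param N vertex count.
#' @return The density scalar `p`.
#' @examples
#' density_from_mean_degree(25, 10000)
#' @export
density_from_mean_degree <- function(mu, N) {
  if (!(is.numeric(mu) && length(mu) == 1L && mu > 0)) {
    stop("mu must be a positive scalar", call. = FALSE)
  }
  if (mu >= N - 1) {
    stop("mu must be smaller than N - 1", call. = FALSE)
  }
  mu / (N - 1)
}
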