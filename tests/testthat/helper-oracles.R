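# Shared fixtures and independent oracles used across the suite.

# Exhaustive enumeration over all 2^(N choose 2) simple graphs: expected
# degree sequence and block link counts under independent edge
# probabilities P (symmetric, zero diagonal). Feasible up to N = 6.
# Deliberately brute-force and independent of the package's algebra.
enum_expectations <- function(P, part) {
  N <- nrow(P)
  pairs <- which(upper.tri(P), arr.ind = TRUE)
  M <- nrow(pairs)
  stopifnot(M <= 15)
  p <- P[pairs]
  # all subsets as a (2^M x M) indicator matrix
  A <- matrix(0L, 2^M, M)
  for (e in seq_len(M)) {
    A[, e] <- bitwAnd(seq_len(2^M) - 1L, 2L^(e - 1L)) > 0L
  }
  logp <- log(pmax(p, 1e-300))
  log1p_ <- log(pmax(1 - p, 1e-300))
  w <- exp(A %*% logp + (1 - A) %*% log1p_)
  # expected edge indicator per pair
  e_ind <- as.numeric(crossprod(A, w))
  deg <- numeric(N)
  L <- matrix(0, part$n, part$n)
  a <- part$assignment
  for (e in seq_len(M)) {
    i <- pairs[e, 1]
    j <- pairs[e, 2]
    deg[i] <- deg[i] + e_ind[e]
    deg[j] <- deg[j] + e_ind[e]
    L[a[i], a[j]] <- L[a[i], a[j]] + e_ind[e]
    L[a[j], a[i]] <- L[a[j], a[i]] + e_ind[e]
  }
  list(weight_total = sum(w), degree = deg, L = L)
}

# random valid model configuration (partition + delta + fitness + density);
# blocks of size >= 4 and low density keep every target below its pair
# capacity
random_configuration <- function(N = sample(12:24, 1), n = sample(1:3, 1)) {
  base <- rep(seq_len(n), each = 4)
  extra <- sample.int(n, N - length(base), replace = TRUE)
  part <- block_partition(sample(c(base, extra)))
  w <- matrix(stats::runif(n * n, 0.1, 1), n, n)
  w <- (w + t(w)) / 2
  unordered <- (sum(w) + sum(diag(w))) / 2
  delta <- w / unordered
  diag(delta) <- 2 * diag(w) / unordered
  p <- stats::runif(1, 0.01, 0.1)
  f <- stats::rlnorm(N, 0, 0.5)
  list(part = part, delta = delta, f = f, p = p)
}

# a small fixed two-block constraint set used by several files
toy_two_block <- function() {
  part <- block_partition(rep(1:2, each = 2))
  delta <- mixing_density(matrix(c(0.8, 0.2, 0.2, 0.8), 2))
  list(
    part = part, delta = delta,
    constraints = build_constraints(0.1, delta, rep(1, 4), part)
  )
}

# fixed 3-block, N = 60, uniform-fitness configuration for sparse-limit
# comparisons
sparse_limit_configuration <- function() {
  part <- block_partition(rep(1:3, times = c(25, 20, 15)))
  w <- matrix(c(4, 1, 0.5, 1, 3, 0.8, 0.5, 0.8, 2), 3)
  w <- (w + t(w)) / 2
  unordered <- (sum(w) + sum(diag(w))) / 2
  delta <- w / unordered
  diag(delta) <- 2 * diag(w) / unordered
  list(part = part, delta = mixing_density(delta, tol = 1e-9), f = rep(1, 60))
}
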