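#' Expected mean degree per block
#'
#' `mu_I = (sum_J K_IJ) / N_I`, the expected average degree of the
#' vertices of block `I` under the constraint set.
#'
#' @param constraints an [constraint_set()].
#' @return Numeric vector of length `n`.
#' @export
block_mean_degrees <- function(constraints) {
  stopifnot(inherits(constraints, "fcbm_constraints"))
  rowSums(constraints$K) / constraints$part$sizes
}

#' Analytical degree-distribution estimators
#'
#' In the sparse regime with i.i.d. fitness drawn from `p_f`, the expected
#' degree of a vertex with fitness `f` in block `I` is approximately
#' `f mu_I / <f>`, which can be inverted to estimate the degree density.
#' Two estimators follow:
#'
#' * block-resolved (`degree_pdf_blockwise`):
#'   \deqn{p_k(k) = \frac{\langle f\rangle}{N}
#'         \sum_I p_f\!\left(k \frac{\langle f\rangle}{\mu_I}\right)
#'         \frac{N_I}{\mu_I},}
#' * global (`degree_pdf_global`), less accurate but simpler:
#'   \deqn{p_k(k) = p_f\!\left(k \frac{\langle f\rangle}{\mu}\right)
#'         \frac{\langle f\rangle}{\mu},}
#'
#' where `mu` is the network mean degree. Both are exact changes of
#' variables of `p_f`, so the degree distribution inherits the shape of
#' the fitness distribution (power-law, lognormal, exponential ...). For
#' exponential fitness the global form collapses to `exp(-k/mu)/mu`
#' independently of the rate. Blocks with `mu_I = 0` contribute a
#' discrete mass `N_I / N` at `k = 0` (the limit of the change of
#' variables); the returned continuous density covers only blocks with
#' `mu_I > 0` and the point mass is reported in attribute `mass_at_zero`.
#'
#' @param k degree values (vectorized, >= 0).
#' @param fd an [fitness_distribution()].
#' @param mus per-block expected mean degrees (see [block_mean_degrees()]).
#' @param sizes per-block sizes `N_I`.
#' @param mu network mean degree (> 0).
#' @return Density values at `k`.
#' @export
degree_pdf_blockwise <- function(k, fd, mus, sizes) {
  stopifnot(inherits(fd, "fcbm_fitness_dist"), length(mus) == length(sizes))
  if (any(mus < 0)) stop("mu_I must be non-negative", call. = FALSE)
  N <- sum(sizes)
  mf <- fd$mean
  live <- mus > 0
  dens <- numeric(length(k))
  for (I in which(live)) {
    dens <- dens + fitness_density(k * mf / mus[I], fd) * sizes[I] / mus[I]
  }
  dens <- dens * mf / N
  attr(dens, "mass_at_zero") <- sum(sizes[!live]) / N
  dens
}

#' @rdname degree_pdf_blockwise
#' @export
degree_pdf_global <- function(k, fd, mu) {
  stopifnot(inherits(fd, "fcbm_fitness_dist"))
  if (!(is.numeric(mu) && length(mu) == 1L && mu > 0)) {
    stop("mu must be a positive scalar", call. = FALSE)
  }
  fitness_density(k * fd$mean / mu, fd) * fd$mean / mu
}

#' Ensemble-averaged empirical degree distribution
#'
#' Normalized degree histogram averaged across the graphs of an ensemble
#' (all sharing the same vertex count).
#'
#' @param graphs list of [fcbm_graph()].
#' @return Data frame with columns `k` (0 .. max degree) and `p`
#'   (average fraction of vertices with degree `k`; sums to 1).
#' @export
empirical_degree_distribution <- function(graphs) {
  stopifnot(length(graphs) >= 1L)
  N <- graphs[[1]]$N
  degs <- lapply(graphs, function(g) {
    stopifnot(inherits(g, "fcbm_graph"), g$N == N)
    degree_sequence(g)
  })
  kmax <- max(vapply(degs, max, numeric(1)), 0)
  counts <- Reduce(`+`, lapply(degs, function(d) tabulate(d + 1L, nbins = kmax + 1L)))
  data.frame(k = 0:kmax, p = counts / (N * length(graphs)))
}

#' Kolmogorov-Smirnov distance to an analytical estimate
#'
#' Discretizes a continuous degree-density estimate on the integer grid
#' spanned by the empirical distribution (density evaluated at integer
#' `k`, plus any point mass at zero, renormalized over the grid) and
#' returns the sup distance between the two CDFs. This mirrors how
#' analytic curves are overlaid on degree histograms. Because the
#' estimators can be inaccurate at very small degrees, the comparison can
#' be restricted to `k >= min_degree` (both distributions are then
#' renormalized over the restricted grid).
#'
#' @param empirical data frame with columns `k`, `p` (see
#'   [empirical_degree_distribution()]).
#' @param estimate either a function `k -> density` or a numeric vector of
#'   densities evaluated at `empirical$k`.
#' @param min_degree smallest degree included (default 0).
#' @param tail_factor the estimate is evaluated up to
#'   `tail_factor * max(empirical$k)` so that tail mass beyond the
#'   observed range is accounted for in the normalization.
#' @return The KS statistic in `[0, 1]`.
#' @export
ks_distance <- function(empirical, estimate, min_degree = 0, tail_factor = 2) {
  stopifnot(is.data.frame(empirical), all(c("k", "p") %in% names(empirical)))
  kmax <- max(empirical$k)
  grid <- 0:ceiling(tail_factor * max(kmax, 1))
  if (is.function(estimate)) {
    est <- estimate(grid)
  } else {
    stopifnot(length(estimate) == nrow(empirical))
    est <- numeric(length(grid))
    est[empirical$k + 1L] <- estimate
  }
  mass0 <- attr(est, "mass_at_zero")
  est <- as.numeric(est)
  if (sum(est) <= 0 && is.null(mass0)) {
    stop("estimate has no mass on the grid", call. = FALSE)
  }
  if (sum(est) > 0) est <- est / sum(est)
  if (!is.null(mass0) && mass0 > 0) {
    # continuous part carries 1 - mass0; the point mass sits at k = 0
    est <- est * (1 - mass0)
    est[1] <- est[1] + mass0
  }
  emp <- numeric(length(grid))
  emp[empirical$k + 1L] <- empirical$p
  keep <- grid >= min_degree
  est <- est[keep]
  emp <- emp[keep]
  if (sum(est) <= 0) stop("estimate has no mass on the grid", call. = FALSE)
  if (sum(emp) <= 0) stop("empirical distribution has no mass on the grid", call. = FALSE)
  est <- est / sum(est)
  emp <- emp / sum(emp)
  max(abs(cumsum(est) - cumsum(emp)))
}
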