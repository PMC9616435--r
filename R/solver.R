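#' Solve the exact maximum-entropy multiplier system
#'
#' Finds positive multipliers `x` (per vertex) and `y` (per block pair)
#' such that the logistic edge probabilities
#' `p_ij = x_i x_j y_IJ / (1 + x_i x_j y_IJ)` reproduce the constraint set
#' in expectation: `sum_{i in I, j in J, i != j} p_ij = K_IJ` for all block
#' pairs and `sum_{j != i} p_ij = k_i` for all vertices.
#'
#' The system is solved by a damped multiplicative fixed-point iteration
#' (alternating `x_i <- x_i k_i / sum_j p_ij` updates with the analogous
#' `y` updates), initialized at the sparse-regime closed form, which is
#' exact in the low-density limit. Convergence is declared when the
#' largest constraint residual — normalized relatively for constraints
#' larger than one — falls below `tol`. Degenerate constraints are pinned:
#' `k_i = 0` fixes `x_i = 0` and `K_IJ = 0` fixes `y_IJ = 0`.
#'
#' The multipliers carry a per-block scale degeneracy (`x_i -> c_I x_i`,
#' `y_IJ -> y_IJ / (c_I c_J)` leaves every `p_ij` unchanged); the returned
#' set is gauge-fixed so that `sum_{i in I} x_i = sum_{i in I} k_i` within
#' each block, making outputs comparable across runs.
#'
#' `solve_fcbm()` expects constraints carrying the density `p` (built via
#' [build_constraints()]); `solve_dcbm()` accepts any consistent `(K, k)`
#' pair, e.g. read off an observed graph. Both share the same solver.
#'
#' @param constraints an [constraint_set()].
#' @param tol convergence threshold on the (relatively normalized) maximum
#'   absolute residual. Default `1e-8`.
#' @param max_iter iteration cap. Default `10000`.
#' @param seed optional seed, used only if the deterministic iteration
#'   fails and a perturbed restart is attempted; the report records it.
#' @return List with components `model` (an [edge_model()], exact rule,
#'   gauge-fixed) and `report` (class `fcbm_solver_report`: `converged`,
#'   `iterations`, `max_residual`, `residual_norm`, `restarts`).
#' @examples
#' part <- block_partition(rep(1, 5))
#' cs <- build_constraints(0.3, mixing_density(matrix(2, 1, 1)), rep(1, 5), part)
#' fit <- solve_fcbm(cs)
#' fit$report$converged
#' edge_probability_matrix(fit$model)[1, 2] # = 0.3 (Erdos-Renyi reduction)
#' @export
solve_fcbm <- function(constraints, tol = 1e-8, max_iter = 10000, seed = NULL) {
  stopifnot(inherits(constraints, "fcbm_constraints"))
  if (is.null(constraints$p)) {
    stop("constraints carry no density p; use build_constraints() or solve_dcbm()",
      call. = FALSE
    )
  }
  solve_multiplier_system(constraints, tol, max_iter, seed)
}

#' @rdname solve_fcbm
#' @export
solve_dcbm <- function(constraints, tol = 1e-8, max_iter = 10000, seed = NULL) {
  stopifnot(inherits(constraints, "fcbm_constraints"))
  solve_multiplier_system(constraints, tol, max_iter, seed)
}

#' @export
print.fcbm_solver_report <- function(x, ...) {
  cat(sprintf(
    "Solver %s after %d iterations: max residual %.3g (norm %.3g)%s\n",
    if (x$converged) "converged" else "did NOT converge",
    x$iterations, x$max_residual, x$residual_norm,
    if (x$restarts > 0) sprintf(", %d perturbed restart(s)", x$restarts) else ""
  ))
  invisible(x)
}

# residuals normalized relatively for targets > 1
normalized_residuals <- function(S, rs, K, k, n) {
  rb <- abs(S - K) / pmax(1, abs(K))
  rv <- abs(rs - k) / pmax(1, abs(k))
  max(rb[upper.tri(rb, diag = TRUE)], rv)
}

solve_multiplier_system <- function(constraints, tol, max_iter, seed = NULL,
                                    .perturb = FALSE) {
  part <- constraints$part
  K <- constraints$K
  k <- constraints$k
  N <- part$N
  n <- part$n
  a <- part$assignment
  B <- block_indicator(part)

  # sparse closed-form start (exact in the p -> 0 limit)
  k_block <- as.numeric(rowsum(k, a))
  x <- k
  y <- matrix(0, n, n)
  pos <- outer(k_block, k_block) > 0
  y[pos] <- K[pos] / outer(k_block, k_block)[pos]
  active_x <- k > 0
  active_y <- K > 0
  y[!active_y] <- 0
  x[!active_x] <- 0
  if (.perturb && !is.null(seed)) {
    set.seed(seed)
    x[active_x] <- x[active_x] * exp(stats::runif(sum(active_x), -0.5, 0.5))
  }

  pair_mat <- function(x, y) {
    m <- outer(x, x) * y[a, a, drop = FALSE]
    P <- m / (1 + m)
    diag(P) <- 0
    P
  }

  damp <- 1
  best <- Inf
  prev_window <- Inf
  res <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # vertex updates
    P <- pair_mat(x, y)
    rs <- rowSums(P)
    upd <- active_x & rs > 0
    ratio <- k[upd] / rs[upd]
    x[upd] <- x[upd] * if (damp == 1) ratio else ratio^damp
    # block-pair updates
    P <- pair_mat(x, y)
    S <- crossprod(B, P %*% B)
    updy <- active_y & S > 0
    ratio_y <- K[updy] / S[updy]
    y[updy] <- y[updy] * if (damp == 1) ratio_y else ratio_y^damp
    y <- (y + t(y)) / 2

    P <- pair_mat(x, y)
    S <- crossprod(B, P %*% B)
    rs <- rowSums(P)
    res <- normalized_residuals(S, rs, K, k, n)
    if (res < best) best <- res
    if (res <= tol) break
    # adaptive damping when the iteration stalls or oscillates
    if (iter %% 50L == 0L) {
      if (res > 0.99 * prev_window && damp > 0.2) damp <- damp / 2
      prev_window <- res
    }
  }

  converged <- res <= tol
  restarts <- 0L
  if (!converged && !.perturb && !is.null(seed)) {
    alt <- solve_multiplier_system(constraints, tol, max_iter, seed, .perturb = TRUE)
    if (alt$report$converged) {
      alt$report$restarts <- 1L
      return(alt)
    }
    restarts <- 1L
  }

  # gauge fix: per-block rescaling so sum_{i in I} x_i = sum_{i in I} k_i
  x_block <- as.numeric(rowsum(x, a))
  scale <- ifelse(x_block > 0, k_block / x_block, 1)
  x <- x * scale[a]
  y <- y / outer(scale, scale)

  model <- edge_model(x, y, part, mode = "exact")
  resid <- constraint_residuals(model, constraints)
  rb <- resid$block[upper.tri(resid$block, diag = TRUE)]
  report <- structure(
    list(
      converged = converged,
      iterations = iter,
      # max residual uses the convergence normalization (relative above 1)
      max_residual = res,
      residual_norm = sqrt(sum(rb^2) + sum(resid$vertex^2)),
      tol = tol,
      restarts = restarts,
      seed = seed
    ),
    class = "fcbm_solver_report"
  )
  list(model = model, report = report)
}
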