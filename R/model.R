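#' Edge probability of the maximum-entropy ensemble
#'
#' The maximum-entropy distribution over simple graphs subject to soft
#' block-pair link-count and degree constraints factorizes into independent
#' Bernoulli edges with
#' \deqn{p_{ij} = \frac{x_i x_j y_{I_i J_j}}{1 + x_i x_j y_{I_i J_j}}}
#' for `i != j` and 0 on the diagonal, where `x_i` and `y_IJ` are the
#' exponentiated Lagrange multipliers of the degree and block-pair
#' constraints.
#'
#' @param x_i,x_j positive vertex multipliers (vectorized).
#' @param y_ij positive block-pair multiplier for the pair's blocks.
#' @param same_vertex logical; `TRUE` where `i == j` (probability 0).
#' @return Edge probability in `[0, 1)`.
#' @examples
#' edge_probability(1, 1, 1) # logistic at 1 -> 0.5
#' @export
edge_probability <- function(x_i, x_j, y_ij, same_vertex = FALSE) {
  m <- x_i * x_j * y_ij
  p <- m / (1 + m)
  p[same_vertex] <- 0
  p
}

#' Edge-probability model
#'
#' Couples a multiplier set with a block partition and a probability rule:
#' `mode = "exact"` uses the logistic form `m / (1 + m)` with
#' `m = x_i x_j y_IJ`; `mode = "sparse"` uses the linearized sparse-regime
#' rule `min(m, 1)` (clipping pairs whose raw product exceeds one).
#'
#' @param x positive per-vertex multipliers (length `N`; zeros allowed for
#'   vertices with zero target degree).
#' @param y non-negative symmetric `n x n` block-pair multiplier matrix.
#' @param part an [block_partition()].
#' @param mode `"exact"` or `"sparse"`.
#' @return An object of class `fcbm_model`.
#' @export
edge_model <- function(x, y, part, mode = c("exact", "sparse")) {
  mode <- match.arg(mode)
  stopifnot(inherits(part, "fcbm_partition"))
  x <- as.numeric(x)
  y <- as.matrix(y)
  if (length(x) != part$N) stop("x has wrong length", call. = FALSE)
  if (!all(dim(y) == part$n)) stop("y has wrong dimensions", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0)) stop("x must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(y)) || any(y < 0)) stop("y must be finite and >= 0", call. = FALSE)
  if (max(abs(y - t(y))) > 1e-12 * max(1, max(y))) {
    stop("y must be symmetric", call. = FALSE)
  }
  structure(
    list(
      x = x, y = unname(y), part = part, mode = mode,
      cache = new.env(parent = emptyenv())
    ),
    class = "fcbm_model"
  )
}

#' @export
print.fcbm_model <- function(x, ...) {
  cat(sprintf(
    "FCBM edge-probability model (%s rule): N = %d, %d blocks\n",
    x$mode, x$part$N, x$part$n
  ))
  if (!is.null(attr(x, "clipped_pairs"))) {
    cat(sprintf("  clipped pairs (raw product > 1): %d\n", attr(x, "clipped_pairs")))
  }
  invisible(x)
}

apply_prob_rule <- function(m, mode) {
  if (mode == "exact") m / (1 + m) else pmin(m, 1)
}

#' Pairwise edge probabilities
#'
#' Dense `N x N` matrix of edge probabilities under the model (zero
#' diagonal). Intended for small / moderate `N`; sampling at large `N`
#' works block pair by block pair and never materializes this matrix.
#'
#' @param model an [edge_model()].
#' @return Symmetric numeric matrix of probabilities in `[0, 1]`.
#' @export
edge_probability_matrix <- function(model) {
  stopifnot(inherits(model, "fcbm_model"))
  a <- model$part$assignment
  m <- outer(model$x, model$x) * model$y[a, a, drop = FALSE]
  P <- apply_prob_rule(m, model$mode)
  diag(P) <- 0
  P
}

#' Single-pair edge probability
#'
#' @param model an [edge_model()].
#' @param i,j vertex indices (vectorized, 1-based).
#' @return Edge probabilities `p_ij` (0 where `i == j`).
#' @export
model_edge_probability <- function(model, i, j) {
  stopifnot(inherits(model, "fcbm_model"))
  a <- model$part$assignment
  m <- model$x[i] * model$x[j] * model$y[cbind(a[i], a[j])]
  p <- apply_prob_rule(m, model$mode)
  p[i == j] <- 0
  p
}

#' Constraint residuals of a multiplier set
#'
#' Evaluates how far the edge probabilities implied by `(x, y)` are from
#' the target expectations: the block-pair residual is
#' `sum_{i in I, j in J, i != j} p_ij - K_IJ` (ordered sums, so the
#' diagonal matches the doubled convention) and the vertex residual is
#' `sum_{j != i} p_ij - k_i`.
#'
#' @param model an [edge_model()] (exact rule).
#' @param constraints an [constraint_set()].
#' @return List with `block` (`n x n` residual matrix) and `vertex`
#'   (length-`N` residual vector).
#' @export
constraint_residuals <- function(model, constraints) {
  stopifnot(inherits(model, "fcbm_model"), inherits(constraints, "fcbm_constraints"))
  P <- edge_probability_matrix(model)
  B <- block_indicator(model$part)
  S <- crossprod(B, P %*% B)
  list(
    block = S - constraints$K,
    vertex = rowSums(P) - constraints$k
  )
}
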