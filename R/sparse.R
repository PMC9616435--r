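#' Sparse-regime closed-form multipliers
#'
#' In the sparse regime (`p << 1`) the logistic edge probability
#' linearizes, `p_ij ~ x_i x_j y_IJ`, and the multiplier system admits a
#' closed-form solution:
#' \deqn{x_i = k_i, \qquad
#'       y_{IJ} = \frac{K_{IJ}}{(\sum_{i \in I} k_i)(\sum_{j \in J} k_j)}.}
#' For constraints built from `(p, delta, f)` this reduces to the
#' product-form probability
#' `p_ij = p C(N,2) (f_i / F_I)(f_j / F_J) delta_IJ` with `F_I` the block
#' fitness totals. The denominators use full block degree totals; the
#' printed inner sums exclude `j = i`, an `O(1/N_I)` difference that the
#' closed form drops (valid for large blocks).
#'
#' Raw products exceeding one are clipped to one when probabilities are
#' emitted; the number of clipped pairs is counted at construction and
#' exposed both as an attribute and via `clipped_pairs()` as a diagnostic
#' of sparse-regime violations.
#'
#' `sparse_fcbm()` requires constraints carrying the density `p`;
#' `sparse_dcbm()` accepts any consistent `(K, k)`.
#'
#' @param constraints an [constraint_set()].
#' @return An [edge_model()] with `mode = "sparse"` and attribute
#'   `clipped_pairs`.
#' @examples
#' part <- block_partition(rep(1:2, each = 2))
#' cs <- constraint_set(matrix(c(0, 2, 2, 0), 2), rep(1, 4), part)
#' m <- sparse_dcbm(cs)
#' model_edge_probability(m, 1, 3) # cross-block pair: 0.5
#' @export
sparse_fcbm <- function(constraints) {
  stopifnot(inherits(constraints, "fcbm_constraints"))
  if (is.null(constraints$p)) {
    stop("constraints carry no density p; use build_constraints() or sparse_dcbm()",
      call. = FALSE
    )
  }
  sparse_closed_form(constraints)
}

#' @rdname sparse_fcbm
#' @export
sparse_dcbm <- function(constraints) {
  stopifnot(inherits(constraints, "fcbm_constraints"))
  sparse_closed_form(constraints)
}

sparse_closed_form <- function(constraints) {
  part <- constraints$part
  K <- constraints$K
  k <- constraints$k
  k_block <- as.numeric(rowsum(k, part$assignment))
  zero_rows <- which(k_block == 0 & rowSums(K) > 0)
  if (length(zero_rows) > 0L) {
    stop("block with zero total degree but nonzero K row: inconsistent input",
      call. = FALSE
    )
  }
  denom <- outer(k_block, k_block)
  y <- matrix(0, part$n, part$n)
  pos <- denom > 0
  y[pos] <- K[pos] / denom[pos]
  model <- edge_model(k, y, part, mode = "sparse")
  attr(model, "clipped_pairs") <- count_clipped_pairs(k, y, part)
  model
}

#' @rdname sparse_fcbm
#' @param model a sparse [edge_model()].
#' @export
clipped_pairs <- function(model) {
  stopifnot(inherits(model, "fcbm_model"))
  attr(model, "clipped_pairs")
}

# count unordered pairs i < j with x_i x_j y_IJ > 1, block pair by block
# pair (never materializes the N x N matrix)
count_clipped_pairs <- function(x, y, part) {
  members <- block_members(part)
  total <- 0L
  for (I in seq_len(part$n)) {
    xi <- x[members[[I]]]
    for (J in I:part$n) {
      if (y[I, J] == 0) next
      # threshold on the product: x_i x_j > 1 / y
      thr <- 1 / y[I, J]
      xj <- x[members[[J]]]
      if (max(xi) * max(xj) <= thr) next
      if (I == J) {
        o <- outer(xi, xi)
        total <- total + sum(o[upper.tri(o)] > thr)
      } else {
        total <- total + sum(outer(xi, xj) > thr)
      }
    }
  }
  as.integer(total)
}
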