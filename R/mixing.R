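#' Mixing-density matrix
#'
#' Validates a block-pair mixing-density matrix Delta: symmetric, entrywise
#' non-negative, with ordered-pair sum `sum(delta) == 2`. The diagonal uses
#' the same double-counting convention as intra-block link counts, so an
#' Erdos-Renyi graph corresponds to the single-block matrix `[[2]]`.
#'
#' @param delta numeric `n x n` matrix.
#' @param tol absolute tolerance on the ordered-pair sum (default `1e-12`).
#' @return `delta`, with class `fcbm_delta` attached.
#' @examples
#' mixing_density(matrix(c(0.8, 0.2, 0.2, 0.8), 2))
#' @export
mixing_density <- function(delta, tol = 1e-12) {
  delta <- as.matrix(delta)
  if (nrow(delta) != ncol(delta)) stop("delta must be square", call. = FALSE)
  if (any(!is.finite(delta))) stop("delta entries must be finite", call. = FALSE)
  if (any(delta < 0)) stop("delta entries must be non-negative", call. = FALSE)
  if (max(abs(delta - t(delta))) > tol) {
    stop("delta must be symmetric", call. = FALSE)
  }
  if (abs(sum(delta) - 2) > tol) {
    stop(sprintf(
      "ordered-pair sum of delta must be 2 (got %.15g)", sum(delta)
    ), call. = FALSE)
  }
  class(delta) <- c("fcbm_delta", class(delta))
  delta
}

is_valid_delta <- function(delta, tol = 1e-12) {
  !inherits(try(mixing_density(unclass(delta), tol), silent = TRUE), "try-error")
}

#' Fitness vector validation
#'
#' A fitness value is a vertex-intrinsic positive propensity to form links;
#' within a block the expected degree of a vertex is proportional to its
#' fitness share. Only ratios `f_i / sum(f[block])` enter the model, so any
#' positive rescaling of `f` is equivalent.
#'
#' @param f numeric vector of strictly positive, finite values.
#' @return `f`, unchanged, after validation.
#' @export
fitness_vector <- function(f) {
  f <- as.numeric(f)
  if (length(f) < 1L) stop("empty fitness vector", call. = FALSE)
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("fitness values must be strictly positive and finite", call. = FALSE)
  }
  f
}
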