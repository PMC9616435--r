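#' Block partition of a vertex set
#'
#' Partitions `N` vertices into `n` non-empty blocks. Blocks group vertices
#' sharing discrete attributes (in the spatial model: residence tile crossed
#' with age group); all block-level edge statistics of the model are defined
#' at the level of ordered block pairs.
#'
#' The diagonal pair count uses the double-counting convention
#' `N_II = N_I (N_I - 1)` (ordered pairs), while `N_IJ = N_I N_J` for
#' distinct blocks; intra-block link counts throughout the package follow
#' the same convention and store twice the number of intra-block edges.
#'
#' @param assignment vector of length `N` (integer, character or factor)
#'   giving the block of each vertex. Levels present in the data define the
#'   blocks; every block is non-empty by construction.
#' @return An object of class `fcbm_partition` with components `N`, `n`,
#'   `assignment` (integer block index in `1:n`), `labels`, `sizes` and
#'   `pair_counts` (the `n x n` matrix `N_IJ`).
#' @examples
#' part <- block_partition(c("a", "a", "b", "b"))
#' part$sizes
#' block_pair_counts(part)
#' @export
block_partition <- function(assignment) {
  if (length(assignment) < 2L) {
    stop("a partition needs at least 2 vertices", call. = FALSE)
  }
  if (anyNA(assignment)) stop("assignment contains NA", call. = FALSE)
  fac <- factor(assignment)
  idx <- as.integer(fac)
  sizes <- as.integer(tabulate(idx, nbins = nlevels(fac)))
  structure(
    list(
      N = length(idx),
      n = nlevels(fac),
      assignment = idx,
      labels = levels(fac),
      sizes = sizes,
      pair_counts = pair_count_matrix(sizes)
    ),
    class = "fcbm_partition"
  )
}

pair_count_matrix <- function(sizes) {
  m <- outer(sizes, sizes)
  diag(m) <- sizes * (sizes - 1)
  storage.mode(m) <- "double"
  m
}

#' @rdname block_partition
#' @param part an `fcbm_partition`
#' @export
block_pair_counts <- function(part) {
  stopifnot(inherits(part, "fcbm_partition"))
  part$pair_counts
}

#' @export
print.fcbm_partition <- function(x, ...) {
  cat(sprintf(
    "Block partition: %d vertices in %d blocks (sizes %s)\n",
    x$N, x$n, paste(x$sizes, collapse = ", ")
  ))
  invisible(x)
}

# membership indicator matrix (N x n), used for block-wise sums
block_indicator <- function(part) {
  B <- matrix(0, part$N, part$n)
  B[cbind(seq_len(part$N), part$assignment)] <- 1
  B
}

# list of vertex index vectors per block
block_members <- function(part) {
  split(seq_len(part$N), part$assignment)
}
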