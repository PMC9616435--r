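#' Tessellate a disk into square tiles
#'
#' Lays a square lattice of pitch `side` whose cell corners sit on integer
#' multiples of `side` (so centers are at half-integer multiples, and the
#' origin is a lattice corner), and keeps the tiles whose center falls
#' within distance `radius` of the origin.
#'
#' @param radius disk radius in km.
#' @param side tile side `l` in km (`0 < side <= radius`).
#' @return Object of class `fcbm_tessellation`: data frame with columns
#'   `tile_id`, `x`, `y` (centers, km) and attributes `side`, `radius`.
#' @examples
#' tess <- tessellate_disk(2.5, 0.5)
#' nrow(tess) # 80 tiles
#' @export
tessellate_disk <- function(radius, side) {
  if (!(radius > 0 && side > 0 && side <= radius)) {
    stop("need 0 < side <= radius", call. = FALSE)
  }
  m <- ceiling(radius / side) + 1L
  half <- (seq_len(2L * m) - m - 0.5) * side
  centers <- expand.grid(x = half, y = half)
  keep <- centers$x^2 + centers$y^2 <= radius^2
  if (!any(keep)) stop("tessellation is empty", call. = FALSE)
  centers <- centers[keep, , drop = FALSE]
  ord <- order(centers$y, centers$x)
  out <- data.frame(
    tile_id = seq_len(sum(keep)),
    x = centers$x[ord],
    y = centers$y[ord]
  )
  attr(out, "side") <- side
  attr(out, "radius") <- radius
  class(out) <- c("fcbm_tessellation", "data.frame")
  out
}

#' Normalized inter-tile distance matrix
#'
#' Euclidean distances between tile centers divided by `l / 2`, with the
#' within-tile distance pinned at `d_II = 1` — so individuals sharing a
#' tile sit at half the distance of individuals in adjacent tiles
#' (`d = 2` for centers one side apart).
#'
#' @param tess an [tessellate_disk()] tessellation.
#' @return Symmetric matrix of dimensionless distances (unit diagonal).
#' @export
tile_distance_matrix <- function(tess) {
  stopifnot(inherits(tess, "fcbm_tessellation"))
  side <- attr(tess, "side")
  d <- as.matrix(stats::dist(cbind(tess$x, tess$y))) / (side / 2)
  diag(d) <- 1
  unname(d)
}

#' Age-based social mixing matrix from a raw contact matrix
#'
#' Survey contact matrices `c_IJ` (mean contacts of a member of group `I`
#' with members of group `J`) are generally asymmetric. Reciprocity is
#' imposed by symmetrizing total contact volumes,
#' `s_IJ ~ (c_IJ w_I + c_JI w_J) / 2` with `w` the population fractions,
#' and the result is normalized so that the sum over unordered group
#' pairs is 1 (any positive scale would be absorbed by the mixing-density
#' normalization anyway; the unit unordered sum makes reported matrices
#' comparable).
#'
#' @param contacts non-negative `|G| x |G|` matrix of raw contact rates.
#' @param fractions population share per age group (sums to 1).
#' @return Symmetric non-negative matrix with unordered-pair sum 1.
#' @export
mixing_matrix_from_contacts <- function(contacts, fractions) {
  contacts <- as.matrix(contacts)
  ng <- nrow(contacts)
  if (ncol(contacts) != ng) stop("contact matrix must be square", call. = FALSE)
  if (any(contacts < 0)) stop("contact rates must be non-negative", call. = FALSE)
  if (length(fractions) != ng) stop("fractions length mismatch", call. = FALSE)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (sum(contacts) == 0) stop("all-zero contact matrix", call. = FALSE)
  vol <- sweep(contacts, 1, fractions, "*")
  s <- (vol + t(vol)) / 2
  unordered <- (sum(s) + sum(diag(s))) / 2
  unname(s / unordered)
}

#' Data-driven mixing-density matrix
#'
#' Combines gravity-style distance decay with age-based social mixing:
#' each unordered block pair gets weight
#' `w_IJ = d_{t_I t_J}^(-beta) * s_{g_I g_J}`, the weights are normalized
#' over unordered pairs, and the ordered matrix is emitted with the
#' doubled diagonal (`Delta_II = 2 w_II`, `Delta_IJ = w_IJ` off the
#' diagonal) so that the ordered-pair sum is exactly 2 — the unique
#' convention compatible with intra-block link counts being stored
#' doubled (the single-block case reduces to `[[2]]`, i.e. Erdos-Renyi).
#'
#' @param d normalized tile distance matrix ([tile_distance_matrix()]).
#' @param s social mixing matrix ([mixing_matrix_from_contacts()]).
#' @param block_tiles,block_groups per-block tile index and age-group
#'   index (parallel vectors defining block `I` as the cell
#'   `(block_tiles[I], block_groups[I])`).
#' @param beta distance-decay exponent (> 0).
#' @return An [mixing_density()] matrix over the given blocks.
#' @examples
#' d <- matrix(c(1, 2, 2, 1), 2)
#' s <- matrix(1, 1, 1)
#' build_delta(d, s, block_tiles = c(1, 2), block_groups = c(1, 1), beta = 1)
#' @export
build_delta <- function(d, s, block_tiles, block_groups, beta) {
  if (!(is.numeric(beta) && length(beta) == 1L && beta > 0)) {
    stop("beta must be a positive scalar", call. = FALSE)
  }
  d <- as.matrix(d)
  s <- as.matrix(s)
  if (length(block_tiles) != length(block_groups)) {
    stop("block index vectors differ in length", call. = FALSE)
  }
  if (any(block_tiles < 1) || any(block_tiles > nrow(d)) ||
    any(block_groups < 1) || any(block_groups > nrow(s))) {
    stop("block indices out of range", call. = FALSE)
  }
  w <- d[block_tiles, block_tiles, drop = FALSE]^(-beta) *
    s[block_groups, block_groups, drop = FALSE]
  delta_from_weights(w)
}

# normalize an ordered symmetric weight matrix into a mixing-density
# matrix: unordered-pair normalization, doubled diagonal, ordered sum 2
delta_from_weights <- function(w) {
  unordered <- (sum(w) + sum(diag(w))) / 2
  if (unordered <= 0) stop("all block-pair weights are zero", call. = FALSE)
  delta <- w / unordered
  diag(delta) <- 2 * diag(w) / unordered
  mixing_density(delta, tol = 1e-9)
}

#' Sample a synthetic population over a tessellation
#'
#' Draws a residence tile for each individual with probability
#' proportional to a spatial density evaluated at the tile center —
#' uniform, increasing with distance from the center (`1 + r/R`) or
#' decreasing (`2 - r/R`) — and an age group i.i.d. from the given
#' fractions.
#'
#' @param N population size.
#' @param tess an [tessellate_disk()] tessellation.
#' @param spatial_density `"uniform"`, `"radial_increasing"` or
#'   `"radial_decreasing"`.
#' @param age_fractions population share per age group (sums to 1).
#' @param seed optional integer seed.
#' @return Data frame with columns `id`, `tile`, `age_group` (integer
#'   indices into the tessellation rows and the age groups).
#' @export
sample_population <- function(N, tess,
                              spatial_density = c(
                                "uniform", "radial_increasing",
                                "radial_decreasing"
                              ),
                              age_fractions, seed = NULL) {
  stopifnot(inherits(tess, "fcbm_tessellation"), N >= 1)
  spatial_density <- match.arg(spatial_density)
  if (any(age_fractions < 0) || abs(sum(age_fractions) - 1) > 1e-8) {
    stop("age_fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  r <- sqrt(tess$x^2 + tess$y^2)
  R <- attr(tess, "radius")
  wt <- switch(spatial_density,
    uniform = rep(1, nrow(tess)),
    radial_increasing = 1 + r / R,
    radial_decreasing = 2 - r / R
  )
  data.frame(
    id = seq_len(N),
    tile = sample.int(nrow(tess), N, replace = TRUE, prob = wt),
    age_group = sample.int(length(age_fractions), N,
      replace = TRUE, prob = age_fractions
    )
  )
}
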