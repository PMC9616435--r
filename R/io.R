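# CSV/GraphML/YAML/JSON plumbing. CSV dialect: comma-separated, header
# row, UTF-8, '.' decimal. Numeric values are written with 17 significant
# digits so real-valued round trips are exact to within 1e-15 relative;
# vertex and block ids are written 0-based (the interchange convention)
# and mapped back to 1-based indices on read.

fmt_num <- function(x) {
  ifelse(is.finite(x) & x == round(x) & abs(x) < 2^53,
    sprintf("%.0f", x),
    sprintf("%.17g", x)
  )
}

write_csv_plain <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path,
    sep = ",", quote = FALSE, row.names = FALSE,
    col.names = TRUE, fileEncoding = "UTF-8"
  )
}

read_csv_checked <- function(path, expected_cols) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) {
      stop(sprintf("malformed CSV %s: %s", path, conditionMessage(e)), call. = FALSE)
    }
  )
  missing <- setdiff(expected_cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf(
      "malformed CSV %s: missing column(s) %s",
      path, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  bad <- if (length(expected_cols) > 0L) {
    which(!stats::complete.cases(df[expected_cols]))
  } else {
    which(!stats::complete.cases(df))
  }
  if (length(bad) > 0L) {
    stop(sprintf(
      "malformed CSV %s: missing value at data line %d",
      path, bad[1]
    ), call. = FALSE)
  }
  df
}

#' Read and write model artifacts
#'
#' Plain-text persistence for every model object: block partitions
#' (`vertex_id`, `block_id`; 0-based), dense matrices (`K`, `y`, `delta`,
#' mixing and distance matrices), per-vertex columns (`k`, `x`, fitness),
#' edge lists (`u`, `v`; 0-based) and GraphML (via igraph). Writing then
#' reading reproduces integers exactly and reals to 1e-15 relative.
#'
#' @param part an [block_partition()].
#' @param path file path.
#' @return Readers return the reconstructed object; writers return the
#'   path invisibly.
#' @name fcbm_io
NULL

#' @rdname fcbm_io
#' @export
write_partition_csv <- function(part, path) {
  stopifnot(inherits(part, "fcbm_partition"))
  write_csv_plain(
    data.frame(
      vertex_id = seq_len(part$N) - 1L,
      block_id = part$assignment - 1L
    ),
    path
  )
  invisible(path)
}

#' @rdname fcbm_io
#' @export
read_partition_csv <- function(path) {
  df <- read_csv_checked(path, c("vertex_id", "block_id"))
  df <- df[order(df$vertex_id), ]
  block_partition(df$block_id)
}

#' @rdname fcbm_io
#' @param m numeric matrix.
#' @export
write_matrix_csv <- function(m, path) {
  m <- as.matrix(m)
  df <- as.data.frame(unclass(m))
  names(df) <- sprintf("c%d", seq_len(ncol(m)) - 1L)
  write_csv_plain(df, path)
  invisible(path)
}

#' @rdname fcbm_io
#' @export
read_matrix_csv <- function(path) {
  df <- read_csv_checked(path, character())
  m <- as.matrix(df)
  if (!is.numeric(m)) stop(sprintf("malformed CSV %s: non-numeric entries", path), call. = FALSE)
  unname(m)
}

#' @rdname fcbm_io
#' @param v numeric vector; `name` the column name used in the file.
#' @param name column name for per-vertex values.
#' @export
write_vertex_csv <- function(v, path, name = "value") {
  df <- data.frame(vertex_id = seq_along(v) - 1L, value = v)
  names(df)[2] <- name
  write_csv_plain(df, path)
  invisible(path)
}

#' @rdname fcbm_io
#' @export
read_vertex_csv <- function(path, name = "value") {
  df <- read_csv_checked(path, c("vertex_id", name))
  df[[name]][order(df$vertex_id)]
}

#' @rdname fcbm_io
#' @param g an [fcbm_graph()].
#' @export
write_edgelist_csv <- function(g, path) {
  stopifnot(inherits(g, "fcbm_graph"))
  write_csv_plain(
    data.frame(u = g$edges[, 1] - 1L, v = g$edges[, 2] - 1L),
    path
  )
  invisible(path)
}

#' @rdname fcbm_io
#' @param N vertex count (edge lists do not record isolated vertices).
#' @export
read_edgelist_csv <- function(path, N) {
  df <- read_csv_checked(path, c("u", "v"))
  fcbm_graph(N, cbind(df$u + 1L, df$v + 1L))
}

#' @rdname fcbm_io
#' @export
write_graphml <- function(g, path) {
  stopifnot(inherits(g, "fcbm_graph"))
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' @rdname fcbm_io
#' @export
read_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  edges <- igraph::as_edgelist(ig, names = FALSE)
  storage.mode(edges) <- "integer"
  fcbm_graph(igraph::vcount(ig), edges)
}

#' @rdname fcbm_io
#' @param model an [edge_model()]; written as a per-vertex `x` CSV, a
#'   dense `y` CSV and the partition CSV under a common prefix.
#' @param prefix path prefix for the three multiplier files.
#' @export
write_model_csv <- function(model, prefix) {
  stopifnot(inherits(model, "fcbm_model"))
  write_vertex_csv(model$x, paste0(prefix, "_x.csv"), name = "x")
  write_matrix_csv(model$y, paste0(prefix, "_y.csv"))
  write_partition_csv(model$part, paste0(prefix, "_partition.csv"))
  invisible(prefix)
}

#' @rdname fcbm_io
#' @param mode probability rule of the stored model.
#' @export
read_model_csv <- function(prefix, mode = "exact") {
  x <- read_vertex_csv(paste0(prefix, "_x.csv"), name = "x")
  y <- read_matrix_csv(paste0(prefix, "_y.csv"))
  part <- read_partition_csv(paste0(prefix, "_partition.csv"))
  edge_model(x, y, part, mode = mode)
}
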