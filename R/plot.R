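#' Plot an empirical degree distribution with its analytical estimates
#'
#' Log-scaled panel overlaying the ensemble-averaged degree histogram
#' with the block-resolved and global analytical estimators, the standard
#' way of inspecting how well the sparse-regime theory tracks a sampled
#' configuration.
#'
#' @param empirical data frame from [empirical_degree_distribution()].
#' @param fd the [fitness_distribution()] used to build the model.
#' @param mus per-block expected mean degrees.
#' @param sizes per-block sizes.
#' @param mu network mean degree.
#' @param log_y log-scale the density axis (default `TRUE`).
#' @return A `ggplot` object.
#' @export
plot_degree_fit <- function(empirical, fd, mus, sizes, mu, log_y = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_degree_fit() requires the ggplot2 package", call. = FALSE)
  }
  k <- empirical$k
  df <- rbind(
    data.frame(k = k, p = empirical$p, what = "empirical"),
    data.frame(
      k = k, p = as.numeric(degree_pdf_blockwise(k, fd, mus, sizes)),
      what = "block-resolved estimate"
    ),
    data.frame(
      k = k, p = degree_pdf_global(k, fd, mu),
      what = "global estimate"
    )
  )
  df <- df[df$p > 0, ]
  gg <- ggplot2::ggplot(df, ggplot2::aes(
    x = k, y = p,
    colour = what, linetype = what
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "degree k", y = "p(k)", colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
  if (log_y) gg <- gg + ggplot2::scale_y_log10()
  gg
}
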