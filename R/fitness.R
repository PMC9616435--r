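#' Fitness distributions
#'
#' The three positive-support fitness families used to control the shape
#' of the degree distribution: Pareto (type I), lognormal and exponential.
#' The analytic mean is stored because the degree-distribution estimators
#' rescale degrees by `<f> / mu`. A Pareto shape greater than 1 is
#' required so the mean is finite.
#'
#' Defaults: `pareto(shape = 2.5, scale = 1)`,
#' `lognormal(meanlog = 0, sdlog = 1)`, `exponential(rate = 1)`. The
#' estimators depend on the family only through its shape (scale and rate
#' cancel in the degree rescaling), so these defaults are inconsequential
#' for distribution-shape properties and are fully configurable.
#'
#' @param family one of `"pareto"`, `"lognormal"`, `"exponential"`.
#' @param shape,scale Pareto shape (> 1) and scale (> 0).
#' @param meanlog,sdlog lognormal log-mean and log-sd (> 0).
#' @param rate exponential rate (> 0).
#' @return Object of class `fcbm_fitness_dist` with fields `family`,
#'   `params` and `mean`.
#' @examples
#' fd <- fitness_distribution("pareto", shape = 2.5, scale = 1)
#' fd$mean # 2.5 / 1.5
#' @export
fitness_distribution <- function(family = c("pareto", "lognormal", "exponential"),
                                 shape = 2.5, scale = 1,
                                 meanlog = 0, sdlog = 1,
                                 rate = 1) {
  family <- match.arg(family)
  params <- switch(family,
    pareto = {
      if (shape <= 1) stop("Pareto shape must exceed 1 for a finite mean", call. = FALSE)
      if (scale <= 0) stop("Pareto scale must be positive", call. = FALSE)
      list(shape = shape, scale = scale)
    },
    lognormal = {
      if (sdlog <= 0) stop("sdlog must be positive", call. = FALSE)
      list(meanlog = meanlog, sdlog = sdlog)
    },
    exponential = {
      if (rate <= 0) stop("rate must be positive", call. = FALSE)
      list(rate = rate)
    }
  )
  m <- switch(family,
    pareto = params$shape * params$scale / (params$shape - 1),
    lognormal = exp(params$meanlog + params$sdlog^2 / 2),
    exponential = 1 / params$rate
  )
  structure(
    list(family = family, params = params, mean = m),
    class = "fcbm_fitness_dist"
  )
}

#' @export
print.fcbm_fitness_dist <- function(x, ...) {
  cat(sprintf(
    "Fitness distribution: %s(%s), mean %.6g\n",
    x$family,
    paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "),
    x$mean
  ))
  invisible(x)
}

#' Density of a fitness distribution
#'
#' @param f evaluation points (vectorized).
#' @param fd an [fitness_distribution()].
#' @return Density values `p_f(f)`.
#' @export
fitness_density <- function(f, fd) {
  stopifnot(inherits(fd, "fcbm_fitness_dist"))
  switch(fd$family,
    pareto = {
      a <- fd$params$shape
      xm <- fd$params$scale
      ifelse(f >= xm, a * xm^a / f^(a + 1), 0)
    },
    lognormal = stats::dlnorm(f, fd$params$meanlog, fd$params$sdlog),
    exponential = stats::dexp(f, fd$params$rate)
  )
}

#' Sample i.i.d. fitness values
#'
#' @param fd an [fitness_distribution()].
#' @param N number of draws.
#' @param seed optional integer seed.
#' @return Numeric vector of `N` positive fitness values.
#' @export
sample_fitness <- function(fd, N, seed = NULL) {
  stopifnot(inherits(fd, "fcbm_fitness_dist"), N >= 1)
  if (!is.null(seed)) set.seed(seed)
  switch(fd$family,
    pareto = fd$params$scale * stats::runif(N)^(-1 / fd$params$shape),
    lognormal = stats::rlnorm(N, fd$params$meanlog, fd$params$sdlog),
    exponential = stats::rexp(N, fd$params$rate)
  )
}
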