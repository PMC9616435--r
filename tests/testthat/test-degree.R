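test_that("fitness families expose correct analytic means and reject bad parameters", {
  expect_equal(fitness_distribution("pareto", shape = 2.5, scale = 1)$mean, 2.5 / 1.5)
  expect_equal(fitness_distribution("exponential", rate = 4)$mean, 0.25)
  expect_equal(fitness_distribution("lognormal", meanlog = 0, sdlog = 1)$mean, exp(0.5))
  expect_error(fitness_distribution("pareto", shape = 1), "shape")
  expect_error(fitness_distribution("exponential", rate = -1), "rate")
})

test_that("fitness sampling is reproducible with the correct mean", {
  N <- 1e5
  fd_exp <- fitness_distribution("exponential", rate = 1)
  f <- sample_fitness(fd_exp, N, seed = 3)
  expect_lt(abs(mean(f) - 1), 3 / sqrt(N)) # exponential sd = 1
  expect_identical(f, sample_fitness(fd_exp, N, seed = 3))

  fd_par <- fitness_distribution("pareto", shape = 2.5, scale = 1)
  fp <- sample_fitness(fd_par, N, seed = 4)
  sd_par <- sqrt(2.5 / (1.5^2 * 0.5))
  expect_lt(abs(mean(fp) - 2.5 / 1.5), 3 * sd_par / sqrt(N))
  expect_gte(min(fp), 1) # support starts at the scale
})

test_that("block mean degrees follow from the constraint row sums", {
  N <- 8
  p <- 0.25
  part <- block_partition(rep(1, N))
  cs <- build_constraints(p, mixing_density(matrix(2, 1, 1)), rep(1, N), part)
  expect_equal(block_mean_degrees(cs), p * (N - 1))

  toy <- toy_two_block()
  expect_equal(block_mean_degrees(toy$constraints), c(0.3, 0.3))

  cs0 <- constraint_set(matrix(0, 1, 1), rep(0, N), part)
  expect_equal(block_mean_degrees(cs0), 0)
})

test_that("exponential fitness collapses the global estimator to exp(-k/mu)/mu", {
  k <- seq(0, 200, by = 0.5)
  mu <- 25
  for (rate in c(0.1, 1, 7)) {
    fd <- fitness_distribution("exponential", rate = rate)
    expect_equal(degree_pdf_global(k, fd, mu), exp(-k / mu) / mu, tolerance = 1e-14)
  }
  expect_equal(degree_pdf_global(0, fitness_distribution("exponential"), 25), 0.04)
})

test_that("the block-resolved estimator reduces to the global one and mixes blocks", {
  fd <- fitness_distribution("exponential", rate = 2)
  k <- 0:150
  # equal block means: both estimators coincide
  expect_equal(
    as.numeric(degree_pdf_blockwise(k, fd, mus = c(20, 20), sizes = c(50, 30))),
    degree_pdf_global(k, fd, 20),
    tolerance = 1e-14
  )
  # two equal-size blocks with means 10 and 30
  expect_equal(
    as.numeric(degree_pdf_blockwise(k, fd, mus = c(10, 30), sizes = c(40, 40))),
    (exp(-k / 10) / 10 + exp(-k / 30) / 30) / 2,
    tolerance = 1e-14
  )
  # a block with zero mean degree contributes a point mass at zero
  est <- degree_pdf_blockwise(k, fd, mus = c(0, 20), sizes = c(25, 75))
  expect_equal(attr(est, "mass_at_zero"), 0.25)
})

test_that("estimators are normalized and preserve the fitness shape", {
  mu <- 25
  for (family in c("pareto", "lognormal", "exponential")) {
    fd <- fitness_distribution(family)
    total <- stats::integrate(function(k) degree_pdf_global(k, fd, mu),
      0, 50 * mu,
      rel.tol = 1e-9, subdivisions = 500L
    )$value
    expect_lt(abs(total - 1), 1e-3)
    totalb <- stats::integrate(
      function(k) {
        as.numeric(degree_pdf_blockwise(k, fd, mus = c(15, 40), sizes = c(60, 40)))
      },
      0, 80 * mu,
      rel.tol = 1e-9, subdivisions = 500L
    )$value
    expect_lt(abs(totalb - 1), 1e-3)
  }

  # Pareto tail: log-log slope of the global estimator equals -(shape + 1)
  a <- 2.5
  fd <- fitness_distribution("pareto", shape = a)
  k <- seq(10 * mu, 50 * mu, length.out = 200)
  slope <- diff(log(degree_pdf_global(k, fd, mu))) / diff(log(k))
  expect_lt(max(abs(slope + (a + 1))), 1e-6)

  # lognormal fitness: degree density is lognormal with shifted location
  fd_ln <- fitness_distribution("lognormal", meanlog = 0.3, sdlog = 0.8)
  kk <- seq(1, 300, by = 0.7)
  shift <- log(mu / fd_ln$mean)
  expect_equal(
    degree_pdf_global(kk, fd_ln, mu),
    stats::dlnorm(kk, meanlog = 0.3 + shift, sdlog = 0.8),
    tolerance = 1e-12
  )
})

test_that("empirical degree distributions average histograms correctly", {
  expect_equal(
    empirical_degree_distribution(list(fcbm_graph(5), fcbm_graph(5))),
    data.frame(k = 0, p = 1)
  )
  cyc <- fcbm_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  emp <- empirical_degree_distribution(list(cyc))
  expect_equal(emp$p, c(0, 0, 1))

  # Erdos-Renyi degrees approach the Poisson law
  N <- 2000
  p <- 0.01
  part <- block_partition(rep(1, N))
  model <- edge_model(rep(sqrt(p / (1 - p)), N), matrix(1, 1, 1), part)
  emp2 <- empirical_degree_distribution(sample_ensemble(model, 5, seed = 21))
  ks <- ks_distance(emp2, function(k) stats::dpois(k, (N - 1) * p))
  expect_lte(ks, 0.05)
})

test_that("KS distance behaves at its extremes", {
  one <- data.frame(k = 0:3, p = c(0, 1, 0, 0))
  expect_equal(ks_distance(one, function(k) as.numeric(k == 1)), 0)
  zero <- data.frame(k = 0:1, p = c(1, 0))
  at_one <- function(k) as.numeric(k == 1)
  expect_equal(ks_distance(zero, at_one), 1)
})

test_that("the block-resolved estimator is at least as accurate as the global one
           in its validity regime", {
  # large blocks with distinct expected mean degrees: the regime in which
  # the change-of-variables argument behind both estimators holds
  set.seed(31)
  N <- 6000
  part <- block_partition(rep(1:3, each = 2000))
  w <- matrix(c(5, 1, 0.5, 1, 4, 1, 0.5, 1, 3), 3)
  w <- (w + t(w)) / 2
  unordered <- (sum(w) + sum(diag(w))) / 2
  delta <- w / unordered
  diag(delta) <- 2 * diag(w) / unordered
  delta <- mixing_density(delta, tol = 1e-9)
  for (family in c("pareto", "lognormal", "exponential")) {
    fd <- fitness_distribution(family)
    f <- sample_fitness(fd, N, seed = 77)
    cs <- build_constraints(25 / (N - 1), delta, f, part)
    graphs <- sample_ensemble(sparse_fcbm(cs), 10, seed = 55)
    emp <- empirical_degree_distribution(graphs)
    mus <- block_mean_degrees(cs)
    ks_block <- ks_distance(emp, function(k) degree_pdf_blockwise(k, fd, mus, part$sizes))
    ks_global <- ks_distance(emp, function(k) degree_pdf_global(k, fd, 25))
    expect_lte(ks_block, ks_global + 0.01)
  }
})
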