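test_that("edge probability is the logistic map of the multiplier product", {
  expect_equal(edge_probability(1, 1, 1), 0.5)
  expect_equal(edge_probability(2, 3, 4, same_vertex = TRUE), 0)
  # small-argument limit: p ~ x_i x_j y to first order
  m <- 1e-9
  expect_equal(edge_probability(m, 1, 1), m / (1 + m))
  expect_lt(abs(edge_probability(1e-6, 1e-3, 1) - 1e-9), 1e-17)
  expect_true(all(edge_probability(c(0.1, 10, 1e6), 1, 1) < 1))
})

test_that("residuals vanish at the analytic fixed point and respond monotonically", {
  part <- block_partition(rep(1, 4))
  p <- 0.3
  cs <- build_constraints(p, mixing_density(matrix(2, 1, 1)), rep(1, 4), part)
  # analytic Erdos-Renyi fixed point: x^2 y = p / (1 - p)
  x <- rep(1, 4)
  y <- matrix(p / (1 - p), 1, 1)
  model <- edge_model(x, y, part)
  res <- constraint_residuals(model, cs)
  expect_lt(max(abs(res$block)), 1e-12)
  expect_lt(max(abs(res$vertex)), 1e-12)

  # empty-model limit: residuals are -K, -k
  res0 <- constraint_residuals(edge_model(rep(0, 4), matrix(0, 1, 1), part), cs)
  expect_equal(res0$block, -cs$K)
  expect_equal(res0$vertex, -cs$k)

  # raising one x_i strictly increases that vertex's residual
  x2 <- x
  x2[1] <- 2
  res2 <- constraint_residuals(edge_model(x2, y, part), cs)
  expect_gt(res2$vertex[1], res$vertex[1])
})

test_that("single-block uniform solve reduces to the Erdos-Renyi model", {
  for (p in c(0.05, 0.3, 0.7)) {
    part <- block_partition(rep(1, 6))
    cs <- build_constraints(p, mixing_density(matrix(2, 1, 1)), rep(1, 6), part)
    fit <- solve_fcbm(cs, seed = 1)
    expect_true(fit$report$converged)
    P <- edge_probability_matrix(fit$model)
    expect_equal(P[upper.tri(P)], rep(p, 15), tolerance = 1e-7)
  }
})

test_that("two-block toy solve satisfies its own residuals within tolerance", {
  toy <- toy_two_block()
  fit <- solve_fcbm(toy$constraints, tol = 1e-10, seed = 1)
  expect_true(fit$report$converged)
  res <- constraint_residuals(fit$model, toy$constraints)
  expect_lt(max(abs(res$block)), 1e-9)
  expect_lt(max(abs(res$vertex)), 1e-9)
})

test_that("exhaustive enumeration confirms the factorized ensemble expectations", {
  # solve constraints observed on a 6-vertex graph with 2 blocks, then
  # check Sum p_ij against a brute-force enumeration of all graphs
  g <- fcbm_graph(6, rbind(
    c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(1, 6), c(2, 5)
  ))
  part <- block_partition(c(1, 1, 1, 2, 2, 2))
  cs <- constraints_from_graph(g, part)
  fit <- solve_dcbm(cs, seed = 3)
  expect_true(fit$report$converged)

  P <- edge_probability_matrix(fit$model)
  oracle <- enum_expectations(P, part)
  expect_equal(oracle$weight_total, 1, tolerance = 1e-12)
  # enumeration equals the analytic pair sums at machine precision
  expect_equal(oracle$degree, rowSums(P), tolerance = 1e-12)
  B <- matrix(0, 6, 2)
  B[cbind(1:6, part$assignment)] <- 1
  expect_equal(oracle$L, unname(crossprod(B, P %*% B)), tolerance = 1e-12)
  # and both equal the constraints within the solver tolerance
  expect_equal(oracle$degree, cs$k, tolerance = 1e-6)
  expect_equal(oracle$L, cs$K, tolerance = 1e-6)
})

test_that("Monte-Carlo ensemble means match the constraints within 3 standard errors", {
  g <- fcbm_graph(6, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(1, 6)))
  part <- block_partition(c(1, 1, 1, 2, 2, 2))
  cs <- constraints_from_graph(g, part)
  fit <- solve_dcbm(cs, seed = 5)
  expect_true(fit$report$converged)

  n_draws <- 20000
  graphs <- sample_ensemble(fit$model, n_draws, seed = 99)
  stats <- ensemble_block_statistics(graphs, part)
  P <- edge_probability_matrix(fit$model)
  # per-vertex degree: sum of independent Bernoulli, variance sum p(1-p)
  se_deg <- sqrt(rowSums(P * (1 - P)) / n_draws)
  expect_true(all(abs(stats$degree - cs$k) <= 3 * se_deg + 1e-12))
  for (I in 1:2) {
    for (J in I:2) {
      v <- 0
      for (i in 1:6) {
        for (j in 1:6) {
          if (i < j && part$assignment[i] %in% c(I, J) &&
            part$assignment[j] %in% c(I, J) &&
            sort(part$assignment[c(i, j)])[1] == I &&
            sort(part$assignment[c(i, j)])[2] == J) {
            mult <- if (I == J) 2 else 1
            v <- v + mult^2 * P[i, j] * (1 - P[i, j])
          }
        }
      }
      se <- sqrt(v / n_draws)
      expect_lte(abs(stats$L[I, J] - cs$K[I, J]), 3 * se + 1e-12)
    }
  }
})

test_that("solutions respect symmetry and the gauge convention", {
  # vertices with equal fitness in the same block obtain equal x
  part <- block_partition(rep(1:2, each = 3))
  delta <- mixing_density(matrix(c(1.2, 0.3, 0.3, 0.2), 2))
  f <- c(1, 1, 2, 3, 3, 3)
  cs <- build_constraints(0.2, delta, f, part)
  fit <- solve_fcbm(cs, seed = 1)
  expect_true(fit$report$converged)
  x <- fit$model$x
  expect_equal(x[1], x[2], tolerance = 1e-9)
  expect_equal(x[4], x[5], tolerance = 1e-9)
  expect_equal(x[5], x[6], tolerance = 1e-9)

  # gauge: block sums of x equal block sums of k after fixing
  k_block <- as.numeric(rowsum(cs$k, part$assignment))
  x_block <- as.numeric(rowsum(x, part$assignment))
  expect_equal(x_block, k_block, tolerance = 1e-9)

  # the gauge map (c x, y / c^2) leaves every edge probability unchanged
  scale <- c(2.5, 0.3)
  model2 <- edge_model(
    x * scale[part$assignment],
    fit$model$y / outer(scale, scale),
    part
  )
  expect_equal(
    edge_probability_matrix(model2),
    edge_probability_matrix(fit$model),
    tolerance = 1e-12
  )
})

test_that("degenerate and infeasible inputs are handled before iteration", {
  part <- block_partition(rep(1, 4))
  expect_error(
    solve_dcbm(constraint_set(matrix(20, 1, 1), rep(5, 4), part)),
    "exceeds N - 1"
  )
  # zero-degree vertex is pinned at x = 0 (4-cycle plus an isolate)
  g <- fcbm_graph(5, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  cs <- constraints_from_graph(g, block_partition(rep(1, 5)))
  fit <- solve_dcbm(cs, seed = 2)
  expect_true(fit$report$converged)
  expect_equal(fit$model$x[5], 0)
  expect_equal(rowSums(edge_probability_matrix(fit$model))[5], 0)
})

test_that("exact solution converges to the sparse closed form as density vanishes", {
  # heterogeneous fitness: the linearization error dominates and shrinks
  # with p (with uniform fitness only the constant O(1/N_I)
  # self-exclusion gap remains; see the sparse-model tests)
  cfg <- sparse_limit_configuration()
  f <- sample_fitness(fitness_distribution("lognormal"), 60, seed = 4)
  dev <- sapply(c(0.1, 0.01, 0.001), function(p) {
    cs <- build_constraints(p, cfg$delta, f, cfg$part)
    fit <- solve_fcbm(cs, seed = 1)
    expect_true(fit$report$converged)
    Pe <- edge_probability_matrix(fit$model)
    Ps <- edge_probability_matrix(sparse_fcbm(cs))
    off <- upper.tri(Pe)
    max(abs(Ps[off] - Pe[off]) / Pe[off])
  })
  expect_true(all(diff(dev) < 0))
})
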