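test_that("disk tessellation matches brute-force lattice enumeration", {
  # independent enumeration of a 0.5 km lattice inside a 2.5 km disk
  brute <- 0L
  for (ix in -10:10) {
    for (iy in -10:10) {
      cx <- (ix + 0.5) * 0.5
      cy <- (iy + 0.5) * 0.5
      if (cx^2 + cy^2 <= 2.5^2) brute <- brute + 1L
    }
  }
  tess <- tessellate_disk(2.5, 0.5)
  expect_equal(nrow(tess), brute)
  expect_equal(nrow(tess), 80)
  expect_true(all(tess$x^2 + tess$y^2 <= 2.5^2))
  # centers sit on the half-integer lattice
  expect_true(all(abs((tess$x / 0.5 - 0.5) %% 1) < 1e-12))

  # radius = side: only the four innermost tiles survive
  tess4 <- tessellate_disk(1, 1)
  expect_equal(nrow(tess4), 4)
  expect_equal(sort(tess4$x), c(-0.5, -0.5, 0.5, 0.5))

  expect_error(tessellate_disk(1, 3), "side <= radius")
})

test_that("normalized distances put same-tile pairs at half a neighbor step", {
  tess <- tessellate_disk(1.2, 0.5)
  d <- tile_distance_matrix(tess)
  expect_equal(diag(d), rep(1, nrow(tess)))
  expect_equal(d, t(d))
  # adjacent tiles: centers one side apart -> normalized distance 2
  adj <- which(abs(outer(tess$x, tess$x, "-")) < 1e-9 &
    abs(abs(outer(tess$y, tess$y, "-")) - 0.5) < 1e-9, arr.ind = TRUE)
  expect_gt(nrow(adj), 0)
  expect_true(all(abs(d[adj] - 2) < 1e-12))
  # diagonal neighbors at 2 * sqrt(2)
  diag_nb <- which(abs(abs(outer(tess$x, tess$x, "-")) - 0.5) < 1e-9 &
    abs(abs(outer(tess$y, tess$y, "-")) - 0.5) < 1e-9, arr.ind = TRUE)
  expect_true(all(abs(d[diag_nb] - 2 * sqrt(2)) < 1e-12))
  # distinct tiles are never closer than 2
  off <- d[upper.tri(d)]
  expect_gte(min(off), 2)
})

test_that("reciprocity symmetrization and normalization of contact matrices", {
  # hand example: 2 groups, equal fractions, c = [[0, 2], [4, 0]]
  s <- mixing_matrix_from_contacts(matrix(c(0, 4, 2, 0), 2), c(0.5, 0.5))
  expect_equal(s, matrix(c(0, 1, 1, 0), 2))

  # already-reciprocal volumes (c_IJ w_I = c_JI w_J): symmetrization is
  # the identity
  cm <- matrix(c(3, 1, 2, 4), 2)
  w <- c(1 / 3, 2 / 3)
  vol <- sweep(cm, 1, w, "*")
  expect_equal(max(abs(vol - t(vol))), 0)
  s2 <- mixing_matrix_from_contacts(cm, w)
  expect_equal(s2 / s2[1, 1], vol / vol[1, 1])
  expect_equal(sum(s2) + sum(diag(s2)), 2) # unordered sum is 1

  # permutation equivariance
  perm <- c(2, 1)
  s3 <- mixing_matrix_from_contacts(cm[perm, perm], w[perm])
  expect_equal(s3, s2[perm, perm])

  expect_error(mixing_matrix_from_contacts(matrix(0, 2, 2), c(0.5, 0.5)), "all-zero")
})

test_that("the data-driven mixing-density matrix follows the gravity rule", {
  # two adjacent tiles, one age group, beta = 1: weights (1, 1, 1/2)
  d <- matrix(c(1, 2, 2, 1), 2)
  s <- matrix(1, 1, 1)
  delta <- build_delta(d, s, block_tiles = c(1, 2), block_groups = c(1, 1), beta = 1)
  expect_equal(unclass(delta), matrix(c(0.8, 0.2, 0.2, 0.8), 2), ignore_attr = TRUE)
  expect_equal(sum(delta), 2)

  # single block: normalization forces [[2]]
  d1 <- build_delta(matrix(1, 1, 1), s, 1, 1, beta = 1)
  expect_equal(unclass(d1), matrix(2, 1, 1), ignore_attr = TRUE)

  # large beta kills off-tile mixing
  db <- build_delta(d, s, c(1, 2), c(1, 1), beta = 60)
  expect_lt(db[1, 2], 1e-17)
  expect_equal(db[1, 1], 1, tolerance = 1e-12)

  expect_error(build_delta(d, s, c(1, 2), c(1, 1), beta = 0), "beta")
})

test_that("mixing-density invariants hold for random spatial inputs", {
  set.seed(19)
  for (rep in 1:50) {
    nt <- sample(2:6, 1)
    ng <- sample(1:3, 1)
    centers <- matrix(stats::runif(nt * 2, -2, 2), nt, 2)
    d <- as.matrix(stats::dist(centers)) / 0.25
    d <- pmax(d, 2)
    diag(d) <- 1
    sraw <- matrix(stats::runif(ng * ng, 0.1, 2), ng, ng)
    s <- (sraw + t(sraw)) / 2
    blocks <- expand.grid(tile = 1:nt, group = 1:ng)
    beta <- stats::runif(1, 0.3, 2.5)
    delta <- build_delta(d, s, blocks$tile, blocks$group, beta)
    expect_equal(sum(delta), 2, tolerance = 1e-12)
    expect_equal(unclass(delta), t(unclass(delta)))
    # rescaling the mixing matrix changes nothing
    delta2 <- build_delta(d, s * 13.7, blocks$tile, blocks$group, beta)
    expect_equal(unclass(delta), unclass(delta2), tolerance = 1e-12)
  }
})

test_that("increasing the decay exponent concentrates mixing on short distances", {
  d <- matrix(c(1, 2, 2, 1), 2)
  s <- matrix(1, 1, 1)
  ratios <- sapply(c(0.5, 1, 2, 4), function(beta) {
    delta <- build_delta(d, s, c(1, 2), c(1, 1), beta)
    delta[1, 2] / delta[1, 1]
  })
  expect_true(all(diff(ratios) < 0))
})

test_that("population sampling respects the spatial density and the seed", {
  tess <- tessellate_disk(2.5, 0.5)
  ages <- c(0.3, 0.7)
  N <- 1e5
  pop <- sample_population(N, tess, "uniform", ages, seed = 8)
  counts <- tabulate(pop$tile, nbins = nrow(tess))
  expected <- N / nrow(tess)
  se <- sqrt(N * (1 / nrow(tess)) * (1 - 1 / nrow(tess)))
  expect_true(all(abs(counts - expected) <= 4 * se))

  # age mix matches the fractions
  expect_lt(abs(mean(pop$age_group == 1) - 0.3), 3 * sqrt(0.3 * 0.7 / N))

  # people concentrate inward under the decreasing profile
  r <- sqrt(tess$x^2 + tess$y^2)
  pop_dec <- sample_population(N, tess, "radial_decreasing", ages, seed = 9)
  expect_lt(mean(r[pop_dec$tile]), mean(r[pop$tile]))
  pop_inc <- sample_population(N, tess, "radial_increasing", ages, seed = 10)
  expect_gt(mean(r[pop_inc$tile]), mean(r[pop$tile]))

  expect_identical(pop, sample_population(N, tess, "uniform", ages, seed = 8))
})
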