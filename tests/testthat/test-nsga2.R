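test_that("dominance is componentwise-with-strictness", {
  expect_true(dominates(c(1, 1), c(2, 2)))
  expect_false(dominates(c(1, 3), c(3, 1)))
  expect_false(dominates(c(3, 1), c(1, 3)))
  expect_false(dominates(c(1, 2), c(1, 2)))     # non-strict
  expect_true(dominates(c(1, 2), c(1, 3)))      # equal in one, better in one
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("fast non-dominated sort handles degenerate fronts", {
  expect_equal(fast_nondominated_sort(matrix(c(1, 2), nrow = 1)), 0L)
  chain <- rbind(c(1, 1), c(2, 2), c(3, 3))
  expect_equal(fast_nondominated_sort(chain), c(0L, 1L, 2L))
  anti <- rbind(c(1, 3), c(2, 2), c(3, 1))
  expect_equal(fast_nondominated_sort(anti), c(0L, 0L, 0L))
  expect_error(fast_nondominated_sort(matrix(numeric(0), ncol = 2)),
               "empty")
})

test_that("fast non-dominated sort agrees with the brute-force oracle", {
  set.seed(91)
  for (i in 1:60) {
    n <- sample(2:40, 1)
    m <- sample(2:4, 1)
    objs <- matrix(stats::rnorm(n * m), n, m)
    if (i %% 3 == 0) {
      # duplicated points and ties exercise the equality edge cases
      objs[sample(n, 1), ] <- objs[sample(n, 1), ]
      objs <- round(objs, 1)
    }
    expect_equal(fast_nondominated_sort(objs), brute_force_ranks(objs))
  }
})

test_that("crowding distance matches hand computation", {
  expect_equal(crowding_distance(rbind(c(1, 2))), Inf)
  expect_equal(crowding_distance(rbind(c(1, 2), c(2, 1))), c(Inf, Inf))
  # three collinear equally spaced points: middle gets 1 per objective
  tri <- rbind(c(0, 4), c(1, 2), c(2, 0))
  expect_equal(crowding_distance(tri), c(Inf, 2, Inf))
  # permutation invariance
  set.seed(92)
  front <- matrix(stats::runif(24), 8, 3)
  perm <- sample(8)
  expect_equal(crowding_distance(front)[perm],
               crowding_distance(front[perm, ]))
})

test_that("evolution solves a 1-D sphere to the known optimum", {
  res <- nsga2_evolve(function(g) sum((g - 0.3)^2), cbind(0, 1),
                      ga_config(pop_size = 20, generations = 50, seed = 7))
  best <- res$pareto$genomes[which.min(res$pareto$objectives), 1]
  expect_lt(abs(best - 0.3), 1e-2)
})

test_that("evolution spreads across a known convex Pareto set", {
  res <- nsga2_evolve(function(g) c(g[1]^2, (g[1] - 2)^2), cbind(-1, 3),
                      ga_config(pop_size = 40, generations = 50, seed = 2))
  g <- sort(res$pareto$genomes[, 1])
  expect_lt(min(g), 0.05)
  expect_gt(max(g), 1.95)
  expect_lt(max(diff(g)), 0.2)
  # the front is the non-dominated subset of the final population
  expect_true(all(res$rank[res$rank == 0] == 0))
})

test_that("selection is elitist across generations", {
  fn <- function(g) c(g[1]^2 + g[2]^2, (g[1] - 1)^2 + g[2]^2)
  bounds <- cbind(c(-2, -2), c(2, 2))
  short <- nsga2_evolve(fn, bounds, ga_config(20, 10, seed = 13))
  long <- nsga2_evolve(fn, bounds, ga_config(20, 11, seed = 13))
  # same seed: the first 10 generations coincide, so no member of the
  # earlier population may dominate any rank-0 member of the next one
  for (i in seq_len(nrow(long$pareto$objectives))) {
    for (j in seq_len(nrow(short$objectives))) {
      expect_false(dominates(short$objectives[j, ],
                             long$pareto$objectives[i, ]))
    }
  }
})

test_that("identical seeds reproduce the run exactly", {
  fn <- function(g) c(sum(g^2), sum((g - 1)^2))
  bounds <- cbind(c(0, 0), c(2, 2))
  a <- nsga2_evolve(fn, bounds, ga_config(16, 20, seed = 99))
  b <- nsga2_evolve(fn, bounds, ga_config(16, 20, seed = 99))
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$objectives, b$objectives)
})

test_that("failing objective evaluations are dominated, not fatal", {
  fn <- function(g) {
    if (g[1] > 0.5) stop("simulation blew up")
    sum((g - 0.25)^2)
  }
  res <- nsga2_evolve(fn, cbind(0, 1),
                      ga_config(pop_size = 12, generations = 20, seed = 3))
  expect_true(all(res$pareto$genomes[, 1] <= 0.5))
  best <- res$pareto$genomes[which.min(res$pareto$objectives), 1]
  expect_lt(abs(best - 0.25), 0.05)
  # a totally infeasible problem aborts with a diagnostic
  expect_error(
    nsga2_evolve(function(g) stop("nope"), cbind(0, 1),
                 ga_config(pop_size = 4, generations = 2, seed = 1)),
    "failed")
})

test_that("ga_config validates its invariants", {
  expect_error(ga_config(pop_size = 5), "even")
  expect_error(ga_config(pop_size = 2), "even")
  expect_error(ga_config(p_crossover = 1.2), "probabilities")
  expect_error(ga_config(generations = 0), "generations")
})
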